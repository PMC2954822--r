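#' Construct the default small-GTPase motif library
#'
#' The Rab set holds the five RabF consensus motifs (IGVDF, KLQIW, RFRSIT,
#' YYRGA, LVYDIT) distributed N- to C-terminally along the G domain. The
#' other-family sets are short consensus windows taken from canonical family
#' members (H-Ras, RhoA, Arf1, Ran); they serve only to ask whether a
#' candidate is more similar to Rabs than to any other small-GTPase class,
#' and can be replaced wholesale via the arguments or a config file
#' (\code{\link{readMotifLibrary}}). The diagnostic set carries WDIAGQE,
#' shared by a deeply conserved clade linked to lysosome-related organelles.
#'
#' @param rab character(5), the Rab motifs in structural order.
#' @param families named list of character vectors, one per non-Rab family.
#' @param diagnostic named character vector of exact-match motifs.
#' @return a validated \linkS4class{MotifLibrary}.
#' @examples
#' lib <- defaultMotifLibrary()
#' rabMotifs(lib)
#' @export
defaultMotifLibrary <- function(
    rab = c("IGVDF", "KLQIW", "RFRSIT", "YYRGA", "LVYDIT"),
    families = list(
      "Ras"     = c("GAGGVGK", "DTAGQEE", "GNKCDL", "YIETSAK"),
      "Rho"     = c("GDGACGK", "DTAGQED", "GNKKDL", "ARRGKK"),
      "Arf/Sar" = c("GLDAAGK", "WDVGGQ", "FANKQD", "NEAREL"),
      "Ran"     = c("GDGGTGK", "KFNVWDT", "KLIGDPN", "DEDDDL")
    ),
    diagnostic = c(WDIAGQE = "WDIAGQE")) {
  new("MotifLibrary", rabMotifs = rab, familyMotifs = families,
      diagnosticMotifs = diagnostic)
}

#' Read a motif library from a sectioned plain-text config
#'
#' Format: one motif per line, grouped under section headers of the form
#' \code{[FamilyName]}. The \code{[Rab]} section (exactly 5 motifs) is
#' mandatory; a \code{[diagnostic]} section may hold \code{name=MOTIF} lines;
#' every other section defines one non-Rab family. Blank lines and lines
#' starting with \code{#} are ignored.
#'
#' @param path path to the config file.
#' @return a \linkS4class{MotifLibrary}.
#' @export
readMotifLibrary <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  rab <- character()
  fams <- list()
  diag <- character()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      next
    }
    if (is.na(section))
      stop("motif config: motif line before any [section] header: ", ln)
    if (identical(section, "Rab")) {
      rab <- c(rab, toupper(ln))
    } else if (identical(section, "diagnostic")) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L)
        stop("motif config: diagnostic lines must be name=MOTIF, got: ", ln)
      diag[trimws(kv[1L])] <- toupper(trimws(kv[2L]))
    } else {
      fams[[section]] <- c(fams[[section]], toupper(ln))
    }
  }
  new("MotifLibrary", rabMotifs = rab, familyMotifs = fams,
      diagnosticMotifs = diag)
}
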