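#' Read a two-group measurement CSV
#'
#' Accepts either a wide layout (two columns, one per group) or a long
#' layout (columns \code{group} and \code{value}). Empty cells,
#' \code{"NA"}, \code{"-"} and the en dash \code{"–"} are treated
#' as missing records and counted, not dropped. Lines starting with
#' \code{#} are comments.
#'
#' @param path path to a CSV file.
#' @return a named list of \code{\link{groupSample}} objects, one per
#'   group, in order of appearance.
#' @export
readTwoGroupCsv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE, strip.white = TRUE)
  asNum <- function(x) {
    x[x %in% c("", "NA", "-", "–")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  nm <- tolower(names(df))
  if (ncol(df) == 2L && all(c("group", "value") %in% nm)) {
    g <- df[[which(nm == "group")]]
    v <- asNum(df[[which(nm == "value")]])
    out <- lapply(unique(g), function(lab) groupSample(v[g == lab], label = lab))
    names(out) <- unique(g)
  } else {
    out <- lapply(names(df), function(lab) groupSample(asNum(df[[lab]]), label = lab))
    names(out) <- names(df)
  }
  out
}

#' Bundled daily-rainfall series: Chiang Rai and Chiang Mai, June 2022
#'
#' Thirty days of daily rainfall (mm) per province, as reported by the
#' Thai Meteorological Department for 1-30 June 2022; unrecorded days
#' appear as missing markers (2 for Chiang Rai, 4 for Chiang Mai). The
#' series mixes dry days (zeros), trace values near the 0.1 mm
#' detection limit and heavy-rain days, which is what makes it a
#' natural delta-lognormal, left-censored example.
#'
#' @return a named list with \code{groupSample}s \code{chiang_rai} and
#'   \code{chiang_mai}.
#' @export
rainfallData <- function() {
  path <- system.file("extdata", "rainfall_chiangrai_chiangmai.csv",
                      package = "dlnratio", mustWork = TRUE)
  g <- readTwoGroupCsv(path)
  list(chiang_rai = g[["chiang_rai"]], chiang_mai = g[["chiang_mai"]])
}
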