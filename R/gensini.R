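#' Default Gensini scoring tables
#'
#' Loads the severity-point table (stenosis category to points: 25% -> 1,
#' 50% -> 2, 75% -> 4, 90% -> 8, 99% -> 16, 100% -> 32) and the
#' coronary-segment multiplier table shipped with the package. The ramus
#' intermedius, an anatomical-variant branch absent from the classic table,
#' carries multiplier 1. Both tables are plain config data and can be replaced
#' by the caller.
#'
#' @param path optional path to a JSON file with fields `severity_points` and
#'   `segment_multipliers`
#' @return a list with numeric named vectors `severity_points` (names are
#'   stenosis percentages) and `segment_multipliers`
#' @export
gensini_tables <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gensini_tables.json",
                        package = "fazmetrics", mustWork = TRUE)
  tab <- jsonlite::fromJSON(path)
  sp <- unlist(tab$severity_points)
  sm <- unlist(tab$segment_multipliers)
  if (!length(sp) || !length(sm) || any(sp <= 0) || any(sm <= 0))
    config_error("scoring tables must hold strictly positive points/multipliers")
  list(severity_points = sp, segment_multipliers = sm)
}

#' Adjusted Gensini score
#'
#' Sums, over all lesions of one patient, the severity points of the stenosis
#' category times the multiplier of the affected coronary segment. Stenosis
#' percentages that fall between the tabulated categories are snapped to the
#' nearest category with a warning.
#'
#' @param lesions a data.frame with columns `segment_id` (names in the
#'   multiplier table) and `stenosis_pct`; zero rows mean no disease
#' @param tables scoring tables from [gensini_tables()]
#' @return the nonnegative Gensini score
#' @examples
#' gensini_score(data.frame(segment_id = "lad_proximal", stenosis_pct = 75))
#' @export
gensini_score <- function(lesions, tables = gensini_tables()) {
  if (is.null(lesions) || nrow(lesions) == 0) return(0)
  if (!all(c("segment_id", "stenosis_pct") %in% names(lesions)))
    parameter_error("lesions need columns segment_id and stenosis_pct")
  seg <- as.character(lesions$segment_id)
  unknown <- setdiff(seg, names(tables$segment_multipliers))
  if (length(unknown))
    config_error(paste0("unknown coronary segment(s): ",
                        paste(unique(unknown), collapse = ", ")))
  cats <- as.numeric(names(tables$severity_points))
  sten <- as.numeric(lesions$stenosis_pct)
  if (any(!is.finite(sten)) || any(sten <= 0))
    parameter_error("stenosis_pct must be positive")
  snapped <- cats[max.col(-abs(outer(sten, cats, "-")), ties.method = "first")]
  if (any(snapped != sten))
    warning(sprintf("%d stenosis value(s) snapped to the nearest category",
                    sum(snapped != sten)), call. = FALSE)
  pts <- tables$severity_points[as.character(snapped)]
  mult <- tables$segment_multipliers[seg]
  sum(pts * mult)
}

#' Severity-group assignment from a Gensini score
#'
#' Maps a Gensini score (GS) to the ternary CAD severity grouping
#' (0: GS 0-3; 1: GS 4-31, read as (3, 31]; 2: GS > 31) and the binary
#' grouping (0: GS 0-3; 1: GS > 14), in which eyes with GS in (3, 14] --
#' mere coronary sclerosis -- are excluded rather than labelled.
#'
#' @param gs nonnegative Gensini score (vectorised)
#' @return a data.frame with columns `gs`, `ternary` (integer 0/1/2) and
#'   `binary` (integer 0/1 or NA for the excluded band)
#' @examples
#' severity_groups(c(0, 23, 59))
#' @export
severity_groups <- function(gs) {
  gs <- as.numeric(gs)
  if (any(!is.finite(gs)) || any(gs < 0))
    parameter_error("gs must be nonnegative")
  ternary <- ifelse(gs <= 3, 0L, ifelse(gs <= 31, 1L, 2L))
  binary <- ifelse(gs <= 3, 0L, ifelse(gs > 14, 1L, NA_integer_))
  data.frame(gs = gs, ternary = ternary, binary = binary)
}
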