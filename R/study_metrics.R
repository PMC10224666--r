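#' Tumor volume from orthogonal caliper diameters
#'
#' V = (pi / 6) * (d1 * d2)^(3/2) in mm^3, where d1 and d2 are orthogonal
#' tumor diameters in mm; symmetric in its arguments and equal to the
#' sphere volume when d1 = d2.
#'
#' @param d1,d2 Orthogonal diameters (mm), non-negative. Vectorized.
#' @return Tumor volume(s) in mm^3.
#' @export
tumor_volume <- function(d1, d2) {
  if (any(d1 < 0) || any(d2 < 0)) stop("diameters must be non-negative")
  (pi / 6) * (d1 * d2)^(3 / 2)
}

#' Area under a tumor growth curve
#'
#' Trapezoidal integral of volume over study time; a single measurement
#' spans a degenerate interval and contributes 0. Missing interim
#' measurements are not imputed.
#'
#' @param times Strictly increasing study days.
#' @param volumes Tumor volumes (mm^3), same length as `times`.
#' @return AUC in mm^3 * day.
#' @export
growth_auc <- function(times, volumes) {
  if (length(times) != length(volumes)) {
    stop("times and volumes differ in length")
  }
  if (length(times) <= 1) return(0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (utils::head(volumes, -1) + utils::tail(volumes, -1)) / 2)
}

#' Per-subject volumes and growth AUC from a measurement table
#'
#' @param measurements Data.frame with columns `subject`, `time`, `d1`,
#'   `d2` (mm).
#' @return List with `volumes` (the input plus a `volume` column) and
#'   `auc` (data.frame: `subject`, `auc`).
#' @export
summarize_growth <- function(measurements) {
  stopifnot(all(c("subject", "time", "d1", "d2") %in% names(measurements)))
  measurements$volume <- tumor_volume(measurements$d1, measurements$d2)
  auc <- do.call(rbind, lapply(split(measurements, measurements$subject),
    function(df) {
      df <- df[order(df$time), ]
      data.frame(subject = df$subject[1],
                 auc = growth_auc(df$time, df$volume),
                 stringsAsFactors = FALSE)
    }))
  rownames(auc) <- NULL
  list(volumes = measurements, auc = auc)
}
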