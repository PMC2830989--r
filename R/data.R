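#' Calibration set of manually designed Southern blot probes
#'
#' Eight manually designed, experimentally validated mouse Southern blot
#' probes used to calibrate the acceptance cut-offs: for each probe, its
#' length, the self/second-hit score ratio from an affine-gap local search
#' of the mouse assembly at score threshold 150, the identity and query
#' coverage of the second-best hit, and the soft-masked (repetitive +
#' low-complexity) base content. One probe's masked content was not
#' determined (`nd`, returned as `NA`).
#'
#' @return data.frame with columns `probe`, `target`, `length`,
#'   `score_ratio`, `second_identity_pct`, `second_coverage_pct`,
#'   `masked_pct`.
#' @examples
#' cal <- calibration_probes()
#' summarize_evaluations(cal)
#' @export
calibration_probes <- function() {
  path <- system.file("extdata", "calibration_probes.tsv",
                      package = "blotprobe", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "nd",
                    stringsAsFactors = FALSE)
}
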