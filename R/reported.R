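# Published evaluation figures for the reference detector on the early
# maize seedling UAV benchmark (EMSD).  These are inputs for arithmetic
# cross-checks (relative improvements, dataset composition), not values this
# package can recompute: the benchmark imagery is not public.

#' Published benchmark figures used for arithmetic cross-checks
#'
#' @return A list with elements:
#' \describe{
#'   \item{detection}{data.frame of recall and AP(50:95) for the baseline
#'     transformer detector and its improved variant on EMSD.}
#'   \item{size_counts}{data.frame of small/medium object counts per split
#'     of EMSD (the benchmark has no large objects).}
#'   \item{reported_improvement}{Printed relative improvements (percent) of
#'     the improved variant over its baseline.}
#'   \item{reported_small_share}{Printed per-split and overall small-object
#'     percentages.}
#'   \item{test_b_total}{Printed ground-truth seedling total of the dense
#'     test subset (the sparse subset total is recoverable by subtraction).}
#' }
#' @export
reported_benchmarks <- function() {
  list(
    detection = data.frame(
      model = c("baseline", "improved"),
      recall = c(0.720, 0.779),
      ap50_95 = c(0.614, 0.714)),
    size_counts = data.frame(
      split = c("train", "val", "test"),
      small = c(44433L, 12851L, 10358L),
      medium = c(5534L, 1617L, 730L),
      large = c(0L, 0L, 0L)),
    reported_improvement = c(ap50_95 = 16.29, recall = 8.19),
    reported_small_share = c(train = 88.92, val = 88.82, test = 93.42,
                             total = 89.56),
    test_b_total = 8315L,
    test_a_total = 2773L)
}
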