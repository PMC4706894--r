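# Published reference results for a five-subject visual P300 speller
# study: efficiency and Nykopp ITR of six first-level classifiers and of
# the Choquet fusion framework, used for arithmetic consistency checks of
# the reported improvement ranges.

#' Reference P300 speller benchmark results
#'
#' Per-subject efficiency and information transfer rate (bits/symbol) of a
#' BCI matrix speller decoded by six first-level classifiers (BLDA, ANN,
#' SRLDA, SWLDA, linear and RBF SVMs) and by their Choquet fusion, as
#' reported in a published five-subject offline study with six
#' communicated symbols per session. Efficiency entries that the study
#' marked ND (not defined: the error distribution precludes effective
#' communication) are `NA`.
#'
#' @return A long tibble with columns `subject`, `classifier`, `metric`
#'   (`"efficiency"` or `"itr"`), `value`, and `role` (`"base"` or
#'   `"framework"`).
#' @export
#' @examples
#' speller_benchmark() |> dplyr::filter(subject == "D", metric == "efficiency")
speller_benchmark <- function() {
  classifiers <- c("BLDA", "ANN", "SRLDA", "SWLDA", "SVM-LIN", "SVM-RBF", "Framework")
  eff <- rbind(
    A = c(0.6821, 0.6690, 0.3277, 0.3392, 0.6986, 0.6519, 0.6964),
    B = c(0.5320, NA,     NA,     0.3283, 0.2019, 0.3874, 0.5121),
    C = c(0.4194, 0.2131, 0.3235, 0.3166, 0.4559, 0.2084, 0.3798),
    D = c(0.4619, 0.4837, 0.2358, 0.2774, 0.5145, 0.4143, 0.5789),
    E = c(0.8272, 0.7979, 0.5948, 0.7873, 0.8046, 0.7729, 0.8736)
  )
  itr <- rbind(
    A = c(1.8800, 1.8885, 1.6434, 1.7259, 1.8424, 1.8341, 1.9133),
    B = c(1.5703, 1.1351, 0.9654, 1.2729, 1.0330, 1.3857, 1.5010),
    C = c(1.1983, 1.0374, 1.0845, 1.0617, 1.2053, 0.9610, 1.1899),
    D = c(1.5542, 1.4622, 1.4282, 1.2773, 1.4989, 1.4819, 1.5764),
    E = c(2.1422, 2.0673, 1.7038, 2.1059, 2.0801, 2.0202, 2.2532)
  )
  colnames(eff) <- classifiers
  colnames(itr) <- classifiers
  to_long <- function(m, metric) {
    tibble::as_tibble(m, rownames = "subject") |>
      tidyr::pivot_longer(-"subject", names_to = "classifier", values_to = "value") |>
      dplyr::mutate(metric = metric)
  }
  dplyr::bind_rows(to_long(eff, "efficiency"), to_long(itr, "itr")) |>
    dplyr::mutate(role = ifelse(.data$classifier == "Framework", "framework", "base")) |>
    dplyr::select("subject", "classifier", "metric", "value", "role")
}

#' Framework improvement over the base classifiers
#'
#' For each subject and metric, the percentage improvement of the fused
#' framework over (a) the ND-skipping mean of the base classifiers and
#' (b) the best base classifier. This recomputes, from the benchmark
#' table, the per-subject quantities whose across-subject ranges the
#' source study reports.
#'
#' @param benchmark A table shaped like [speller_benchmark()] (the
#'   default).
#' @return A tibble with `subject`, `metric`, `vs_average`, `vs_best`
#'   (both percentages).
#' @export
fusion_improvement <- function(benchmark = speller_benchmark()) {
  benchmark |>
    dplyr::group_by(.data$subject, .data$metric) |>
    dplyr::summarise(
      vs_average = percentage_improvement(
        .data$value[.data$role == "framework"],
        mean(.data$value[.data$role == "base"], na.rm = TRUE)
      ),
      vs_best = percentage_improvement(
        .data$value[.data$role == "framework"],
        max(.data$value[.data$role == "base"], na.rm = TRUE)
      ),
      .groups = "drop"
    )
}

#' Across-subject improvement ranges
#'
#' Minimum and maximum over subjects of the [fusion_improvement()]
#' percentages, per metric and reference.
#'
#' @inheritParams fusion_improvement
#' @return A tibble with `metric`, `reference` (`"average"`/`"best"`),
#'   `min`, `max`.
#' @export
improvement_ranges <- function(benchmark = speller_benchmark()) {
  fusion_improvement(benchmark) |>
    tidyr::pivot_longer(c("vs_average", "vs_best"),
                        names_to = "reference", values_to = "improvement") |>
    dplyr::mutate(reference = sub("^vs_", "", .data$reference)) |>
    dplyr::group_by(.data$metric, .data$reference) |>
    dplyr::summarise(min = min(.data$improvement), max = max(.data$improvement),
                     .groups = "drop")
}
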