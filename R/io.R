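# File formats: long-format score CSV, JSON model serialization (with a
# schema version), YAML run configuration.

SCORE_COLUMNS <- c("sample_id", "true_class", "classifier", "class", "score")
MODEL_SCHEMA_VERSION <- 1L

#' Read / write long-format score CSV
#'
#' The on-disk format is one score per row with header
#' `sample_id,true_class,classifier,class,score`; `true_class` may be
#' empty (unlabelled data). Each sample must carry the full
#' classifier-by-class grid.
#'
#' @param path File path.
#' @return For `read_scores()`, a validated score tibble (without the
#'   `true_class` column if it was empty).
#' @export
read_scores <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(SCORE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!is.numeric(df$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$score))))[1]
    stop(sprintf("%s: non-numeric score at data row %d", path, bad), call. = FALSE)
  }
  if (all(is.na(df$true_class))) df$true_class <- NULL
  validate_scores(df)
}

#' @rdname read_scores
#' @param scores A score tibble (see [simulate_scores()]).
#' @export
write_scores <- function(scores, path) {
  scores <- validate_scores(scores)
  if (!"true_class" %in% names(scores)) scores$true_class <- NA_character_
  readr::write_csv(scores[SCORE_COLUMNS], path)
  invisible(path)
}

# capacity <-> plain list with the documented JSON schema
capacity_to_list <- function(cap) {
  list(n = cap$n_elements, k = cap$order, normalized = cap$normalized,
       mobius = as.list(cap$mobius))
}

capacity_from_list <- function(x) {
  capacity(unlist(x$mobius), n_elements = x$n, order = x$k,
           validate = FALSE)
}

#' Serialize / deserialize a fusion model as JSON
#'
#' The model file carries a schema `version`, the label sets, the
#' normalization configuration, the abstention threshold, the per-class
#' ensembles, and every capacity as
#' `{"n": ..., "k": ..., "normalized": ..., "mobius": {"0,2": coeff, ...}}`
#' with Moebius coefficients at full double precision, so a round trip
#' reproduces identical decisions.
#'
#' @param model A [fit_fusion()] model.
#' @param path File path.
#' @return `read_model()` returns the reconstructed `"fusion_model"`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  payload <- list(
    version = MODEL_SCHEMA_VERSION,
    k = model$k, n = model$n, s = model$s,
    global_order = model$global_order, ridge = model$ridge,
    classifiers = model$classifiers, classes = model$classes,
    normalization = unclass(model$normalization),
    threshold = model$threshold,
    ensembles = lapply(model$classes, function(cls) {
      list(class = cls, members = model$ensembles[[cls]]$members)
    }),
    global_capacities = lapply(model$global_capacities, capacity_to_list),
    class_capacities = lapply(model$class_capacities, capacity_to_list)
  )
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        stop(sprintf("cannot parse model file %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
                      })
  if (is.null(payload$version) || payload$version != MODEL_SCHEMA_VERSION) {
    stop(sprintf("model schema version %s is not supported (expected %d)",
                 payload$version %||% "<missing>", MODEL_SCHEMA_VERSION),
         call. = FALSE)
  }
  classes <- unlist(payload$classes)
  ensembles <- stats::setNames(lapply(payload$ensembles, function(e) {
    structure(list(members = as.integer(unlist(e$members)),
                   s = payload$s, criterion = numeric(0)),
              class = "ensemble")
  }), vapply(payload$ensembles, function(e) e$class, ""))
  nc <- payload$normalization
  structure(
    list(
      k = payload$k, n = payload$n,
      classifiers = unlist(payload$classifiers), classes = classes,
      s = payload$s, global_order = payload$global_order, ridge = payload$ridge,
      normalization = normalize_config(nc$slope, nc$slope_max,
                                       nc$crossover_rule, nc$degenerate_belief),
      global_capacities = lapply(payload$global_capacities, capacity_from_list),
      ensembles = ensembles[classes],
      class_capacities = lapply(payload$class_capacities, capacity_from_list),
      threshold = payload$threshold
    ),
    class = "fusion_model"
  )
}

#' Read a YAML run configuration
#'
#' Recognized blocks (all optional, with package defaults): `seed`;
#' `normalization` (`slope`, `slope_max`, `crossover_rule`,
#' `degenerate_belief`); `learning` (`global_order`, `class_order`,
#' `ridge`); `ensemble` (`s`, `early_stop`); `decision` (`threshold`,
#' `grid_step`, `metric`); `simulation` (arguments of
#' [simulate_scores()]).
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in; the `normalization`
#'   entry is a [normalize_config()].
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  merge_block <- function(defaults, block) {
    user <- raw[[block]] %||% list()
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown) > 0) {
      stop(sprintf("unknown key(s) in %s block: %s", block,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, user)
  }
  norm <- merge_block(list(slope = 2, slope_max = 10,
                           crossover_rule = "midpoint_top2",
                           degenerate_belief = 0.5), "normalization")
  list(
    seed = raw$seed %||% 1L,
    normalization = normalize_config(norm$slope, norm$slope_max,
                                     norm$crossover_rule, norm$degenerate_belief),
    learning = merge_block(list(global_order = 4, class_order = NULL, ridge = 1e-6),
                           "learning"),
    ensemble = merge_block(list(s = 4, early_stop = FALSE), "ensemble"),
    decision = merge_block(list(threshold = NULL, grid_step = 0.01,
                                metric = "efficiency"), "decision"),
    simulation = raw$simulation %||% list()
  )
}
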