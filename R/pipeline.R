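#' Classify a subject as Faller or Non-faller from trial outcomes
#'
#' A subject is a Faller if and only if they fell (stepped or loaded the
#' safety harness) on the third, final perturbation; managing the third
#' perturbation in place makes them a Non-faller regardless of earlier
#' trials.
#'
#' @param outcomes Character vector of exactly 3 trial results, each
#'   `"fall"` or `"success"`.
#' @return `"Faller"` or `"Non-faller"`.
#' @examples
#' classify_faller(c("fall", "fall", "success")) # Non-faller
#' classify_faller(c("fall", "fall", "fall")) # Faller
#' @export
classify_faller <- function(outcomes) {
  if (length(outcomes) != 3) abort("exactly 3 trial outcomes are required")
  if (!all(outcomes %in% c("fall", "success"))) {
    abort("outcomes must be 'fall' or 'success'")
  }
  if (outcomes[3] == "fall") "Faller" else "Non-faller"
}

#' Default construct map for the hierarchical base models
#'
#' The four variable groups collapsed into one-component PCA base models
#' before the top model: six fall-related-concern items, the four
#' quiet-stance sway areas, the six lower-extremity strength tests and the
#' four joint-position-sense errors.
#'
#' @return Named list of character vectors of feature-table column names.
#' @export
default_constructs <- function() {
  list(
    fall_concerns = c(
      "afraid_falling", "concern_injury", "concern_helpless",
      "concern_help", "concern_burden", "fes_i"
    ),
    balance = paste0("sway_", .sway_conditions),
    strength = c(
      "torque_hip_ext", "torque_hip_abd", "torque_knee_ext",
      "torque_knee_flex", "torque_ankle_df", "torque_ankle_pf"
    ),
    jps = c(
      "jps_knee_left", "jps_knee_right", "jps_ankle_left", "jps_ankle_right"
    )
  )
}

#' Assemble the subject-level feature table
#'
#' Combines scalar subject records with the derived trial and sway
#' features into the table the multivariate analysis consumes:
#' * strength torques are normalized by body height in metres (Nm/m);
#' * reaction time is the mean of the five raw trials (ms);
#' * sway ellipse areas become one column per condition (`sway_<condition>`);
#' * kinematic and EMG co-contraction features of trials 1 and 3 are
#'   attached with `_t1`/`_t3` suffixes;
#' * sex is encoded as `sex_male` (0/1);
#' * the class label comes from [classify_faller()] on the three outcomes.
#'
#' Subjects flagged vestibular-positive (nystagmus on provocation) are
#' excluded before assembly.
#'
#' @param records Subject tibble (one row per subject) with the scalar
#'   variables of [default_effect_table()] (reaction time as `rt_ms_1..5`),
#'   `outcome_1..3`, `sex` and `vestibular_positive`; e.g. the `subjects`
#'   element of [simulate_cohort_features()].
#' @param trial_features Tibble `id`, `trial`, plus feature columns (from
#'   [extract_kinematic_features()] / [extract_emg_features()]).
#' @param sway_features Tibble `id`, `condition`, `area_cm2`.
#' @return A tibble, one row per retained subject, with `id`, `class` and
#'   the model variables.
#' @export
build_feature_table <- function(records, trial_features, sway_features) {
  if (any(records$height_cm <= 0, na.rm = TRUE)) {
    abort("height must be positive for torque normalization")
  }
  rec <- records[!records$vestibular_positive, , drop = FALSE]

  rec$class <- purrr::pmap_chr(
    rec[c("outcome_1", "outcome_2", "outcome_3")],
    function(outcome_1, outcome_2, outcome_3) {
      classify_faller(c(outcome_1, outcome_2, outcome_3))
    }
  )
  height_m <- rec$height_cm / 100
  for (v in grep("^torque_", names(rec), value = TRUE)) {
    rec[[v]] <- rec[[v]] / height_m
  }
  rt_cols <- paste0("rt_ms_", 1:5)
  rec$reaction_time <- rowMeans(rec[rt_cols])
  rec$sex_male <- as.numeric(rec$sex == "male")

  sway_wide <- tidyr::pivot_wider(sway_features,
    names_from = "condition", values_from = "area_cm2",
    names_prefix = "sway_"
  )
  tf <- trial_features[trial_features$trial %in% c(1, 3) &
    trial_features$id %in% rec$id, , drop = FALSE]
  tf$ta_onset_time <- NULL
  tf_wide <- tidyr::pivot_wider(tf,
    names_from = "trial", values_from = -dplyr::all_of(c("id", "trial")),
    names_glue = "{.value}_t{trial}"
  )

  drop <- c(rt_cols, "sex", "vestibular_positive", paste0("outcome_", 1:3))
  out <- rec[setdiff(names(rec), c(drop, "group"))]
  out <- dplyr::left_join(out, sway_wide, by = "id")
  out <- dplyr::left_join(out, tf_wide, by = "id")
  dplyr::relocate(as_tibble(out), "id", "class")
}

.iqr_summary <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

.mw_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1) return(1) # no information either way
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(length(x), length(y)) <= 25
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Univariate group and inter-trial comparisons
#'
#' The descriptive statistics companion to the multivariate model:
#' * every continuous variable: group medians with interquartile ranges and
#'   a two-sided Mann-Whitney U test (exact for group sizes up to 25
#'   without ties, normal approximation with tie correction otherwise);
#' * sex: Fisher's exact test on the 2x2 group table;
#' * every trial-paired feature (`*_t1` / `*_t3`): a paired Wilcoxon
#'   signed-rank test within each group.
#'
#' No multiple-testing adjustment is applied.
#'
#' @param features Feature table from [build_feature_table()] (must contain
#'   `class`).
#' @return A tibble with one row per comparison: `variable`, `comparison`
#'   (`"between_groups"` or `"trial1_vs_trial3"`), `test`, `group`, group
#'   medians/quartiles, `trial1_median`, `trial3_median`, `p_value`.
#' @export
univariate_comparisons <- function(features) {
  if (!"class" %in% names(features)) abort("features must contain 'class'")
  grp <- features$class
  if (length(unique(grp)) < 2 || any(table(grp) == 0)) {
    abort("both groups must be present with n > 0")
  }
  nf <- grp == "Non-faller"
  num_vars <- setdiff(
    names(features)[vapply(features, is.numeric, logical(1))], "sex_male"
  )

  rows <- purrr::map_dfr(num_vars, function(v) {
    x <- features[[v]][nf]
    y <- features[[v]][!nf]
    snf <- .iqr_summary(x)
    sf <- .iqr_summary(y)
    tibble(
      variable = v, comparison = "between_groups", test = "mann_whitney",
      group = NA_character_,
      nonfaller_median = snf[["median"]], nonfaller_q1 = snf[["q1"]],
      nonfaller_q3 = snf[["q3"]],
      faller_median = sf[["median"]], faller_q1 = sf[["q1"]],
      faller_q3 = sf[["q3"]],
      trial1_median = NA_real_, trial3_median = NA_real_,
      p_value = .mw_test(x[!is.na(x)], y[!is.na(y)])
    )
  })

  if ("sex_male" %in% names(features)) {
    tab <- table(
      factor(features$sex_male, levels = c(1, 0)),
      factor(grp, levels = .groups)
    )
    rows <- dplyr::bind_rows(rows, tibble(
      variable = "sex_male", comparison = "between_groups",
      test = "fisher_exact", group = NA_character_,
      nonfaller_median = NA_real_, nonfaller_q1 = NA_real_,
      nonfaller_q3 = NA_real_, faller_median = NA_real_,
      faller_q1 = NA_real_, faller_q3 = NA_real_,
      trial1_median = NA_real_, trial3_median = NA_real_,
      p_value = stats::fisher.test(tab)$p.value
    ))
  }

  paired_base <- sub("_t1$", "", grep("_t1$", names(features), value = TRUE))
  paired_base <- paired_base[paste0(paired_base, "_t3") %in% names(features)]
  trial_rows <- purrr::map_dfr(paired_base, function(v) {
    purrr::map_dfr(.groups, function(g) {
      sel <- grp == g
      x1 <- features[[paste0(v, "_t1")]][sel]
      x3 <- features[[paste0(v, "_t3")]][sel]
      ok <- !is.na(x1) & !is.na(x3)
      if (sum(ok) < 2) return(tibble())
      p <- suppressWarnings(
        stats::wilcox.test(x1[ok], x3[ok], paired = TRUE)$p.value
      )
      tibble(
        variable = v, comparison = "trial1_vs_trial3",
        test = "wilcoxon_signed_rank", group = g,
        nonfaller_median = NA_real_, nonfaller_q1 = NA_real_,
        nonfaller_q3 = NA_real_, faller_median = NA_real_,
        faller_q1 = NA_real_, faller_q3 = NA_real_,
        trial1_median = stats::median(x1[ok]),
        trial3_median = stats::median(x3[ok]),
        p_value = p
      )
    })
  })
  dplyr::bind_rows(rows, trial_rows)
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: feature assembly (from a synthetic cohort or a
#' feature CSV), univariate comparisons, UV scaling, hierarchical PCA base
#' models, the OPLS-DA top model, jackknife coefficient significance and
#' permutation validation. Seeded synthetic runs are bit-reproducible.
#'
#' @param config A list with elements:
#'   * `cohort` — a [cohort_config()] (synthetic mode), or
#'   * `features_csv` — path to a feature table CSV with `id` and `class`
#'     columns (data mode, see [build_feature_table()] for the layout);
#'   * `constructs` — named list of base-model variable groups (required;
#'     see [default_constructs()]);
#'   * `model` — optional list: `n_orth` (default 1), `folds` (7),
#'     `n_perms` (200), `level` (0.95), `perm_seed` (derived from the
#'     cohort seed when absent).
#' @param out_dir Optional directory; when given, the feature table,
#'   univariate table, coefficient report, permutation points, model
#'   summaries, the resolved config and a manifest are written there as
#'   CSV/JSON.
#' @return An object of class `analysis_report`: list with `features`,
#'   `univariate`, `base_models`, `scaled` (post-base-model table),
#'   `top_model`, `coefficients`, `permutation`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  missing_keys <- setdiff("constructs", names(config))
  if (length(missing_keys) > 0) {
    abort(paste0("config is missing required keys: ", toString(missing_keys)))
  }
  if (is.null(config$cohort) && is.null(config$features_csv)) {
    abort("config needs either 'cohort' (synthetic mode) or 'features_csv'")
  }
  model_cfg <- utils::modifyList(
    list(n_orth = 1, folds = 7, n_perms = 200, level = 0.95, perm_seed = NULL),
    config$model %||% list()
  )

  if (!is.null(config$features_csv)) {
    features <- read_feature_csv(config$features_csv)
    seed0 <- 1L
  } else {
    parts <- simulate_cohort_features(config$cohort)
    features <- build_feature_table(
      parts$subjects, parts$trial_features, parts$sway_features
    )
    seed0 <- config$cohort$seed
  }
  perm_seed <- model_cfg$perm_seed %||% (seed0 + 1000L)

  univar <- univariate_comparisons(features)

  scaled <- scale_uv(features)
  with_scores <- fit_base_models(scaled, config$constructs)
  base_models <- attr(with_scores, "base_models")

  xcols <- setdiff(
    names(with_scores)[vapply(with_scores, is.numeric, logical(1))],
    character(0)
  )
  X <- with_scores[xcols]
  y <- features$class
  ids <- features$id

  top <- fit_oplsda(X, y,
    n_orth = model_cfg$n_orth, positive = "Faller",
    folds = model_cfg$folds, ids = ids
  )
  coefs <- coefficient_significance(X, y,
    n_orth = model_cfg$n_orth,
    folds = model_cfg$folds, level = model_cfg$level,
    positive = "Faller", ids = ids
  )
  perm <- permutation_validation(X, y,
    n_perms = model_cfg$n_perms,
    seed = perm_seed, n_orth = model_cfg$n_orth,
    folds = model_cfg$folds, positive = "Faller", ids = ids
  )

  report <- structure(
    list(
      features = features, univariate = univar,
      base_models = base_models, scaled = with_scores,
      top_model = top, coefficients = coefs, permutation = perm,
      config = utils::modifyList(config, list(model = model_cfg))
    ),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Postural adaptation analysis report\n")
  cat(
    " ", nrow(x$features), "subjects (",
    sum(x$features$class == "Faller"), "Fallers /",
    sum(x$features$class == "Non-faller"), "Non-fallers )\n"
  )
  for (nm in names(x$base_models)) {
    m <- x$base_models[[nm]]
    cat(sprintf(
      "  base model %-14s R2(X) = %4.1f%%  Q2 = %4.1f%%\n",
      nm, 100 * sum(m$R2), 100 * m$Q2
    ))
  }
  cat(sprintf(
    "  top model OPLS-DA: R2Y = %.1f%%, Q2 = %.1f%%\n",
    100 * x$top_model$R2Y, 100 * x$top_model$Q2
  ))
  cat(
    "  significant coefficients:",
    sum(x$coefficients$significant), "of", nrow(x$coefficients), "\n"
  )
  cat("  permutation verdict:", x$permutation$verdict, "\n")
  invisible(x)
}
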