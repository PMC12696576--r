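# End-to-end orchestration: load/simulate -> filter -> score -> reliability
# -> feature selection -> augmentation (per ratio) -> model development and
# evaluation -> model comparison, with one master seed deriving per-stage
# seeds and a JSON manifest of outputs.

#' Pipeline configuration
#'
#' @param input Path to a cohort CSV, or `NULL` to simulate a cohort from
#'   `sim_config`.
#' @param sim_config An [cohort_config()] used when `input` is `NULL` (and
#'   always used to build norms when `norms` is `NULL`).
#' @param out_dir Output directory (created if absent).
#' @param stages Character vector of enabled optional stages, any of
#'   `"reliability"`, `"select"`, `"augment"`, `"evaluate"`.
#' @param ratios Augmentation ratios (default `c(4, 8, 12, 16, 20)`).
#' @param families Model families evaluated (default RF, SVM, KNN).
#' @param alpha Significance level for the screens.
#' @param folds CV folds.
#' @param smote_order `"balance_then_split"` replicates the
#'   balance-before-split procedure (information leaks from test to train;
#'   a prominent warning is emitted); `"split_then_balance"` balances the
#'   training set only.
#' @param norms An [norm_table()], or `NULL` to build one from `sim_config`.
#' @param master_seed Master seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @return A list of class `rcads_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            sim_config = cohort_config(),
                            out_dir = tempfile("rcads_run_"),
                            stages = c("reliability", "select", "augment", "evaluate"),
                            ratios = c(4L, 8L, 12L, 16L, 20L),
                            families = c("RF", "SVM", "KNN"),
                            alpha = 0.05,
                            folds = 5L,
                            smote_order = c("balance_then_split", "split_then_balance"),
                            norms = NULL,
                            master_seed = 1L) {
  smote_order <- match.arg(smote_order)
  stopifnot(all(stages %in% c("reliability", "select", "augment", "evaluate")),
            all(families %in% c("RF", "SVM", "LR", "DT", "NB", "KNN")))
  structure(list(input = input, sim_config = sim_config, out_dir = out_dir,
                 stages = stages, ratios = as.integer(ratios),
                 families = families, alpha = alpha, folds = as.integer(folds),
                 smote_order = smote_order, norms = norms,
                 master_seed = as.integer(master_seed)),
            class = "rcads_pipeline_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  path
}

eval_to_list <- function(ev) {
  list(per_class = ev$per_class, accuracy = ev$accuracy,
       macro_avg = as.list(ev$macro_avg), weighted_avg = as.list(ev$weighted_avg),
       confusion = unname(apply(ev$confusion, 1, as.integer, simplify = FALSE)),
       cv_fold_scores = ev$cv_fold_scores, best_params = ev$best_params,
       family = ev$family)
}

#' Run the screening pipeline end to end
#'
#' Executes the enabled stages in order, persisting every stage's outputs
#' under `cfg$out_dir` (tabular outputs as CSV, reports as JSON) and a
#' manifest (`manifest.json`) recording per-stage seeds and MD5 hashes of
#' all outputs; reruns with the same configuration and master seed reproduce
#' identical hashes. A stage failure aborts with the stage name; outputs of
#' completed stages remain on disk.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (a list; also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "rcads_pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bank <- rcads_item_bank()
  manifest <- list(package_version = as.character(utils::packageVersion("rcadscreen")),
                   master_seed = cfg$master_seed, stages = list())
  note_stage <- function(name, seed, files) {
    hashes <- as.list(tools::md5sum(files))
    names(hashes) <- basename(files)
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, seed = seed, outputs = hashes)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  # --- load / simulate -------------------------------------------------
  seed_sim <- derive_seed(cfg$master_seed, "simulate")
  cohort <- run_stage("load", {
    if (is.null(cfg$input)) {
      sim_cfg <- cfg$sim_config
      sim_cfg$seed <- seed_sim
      sim <- simulate_cohort(sim_cfg, bank)
      write_cohort(sim$cohort, out("cohort.csv"))
      sim$cohort
    } else {
      co <- read_cohort(cfg$input, bank)
      write_cohort(co, out("cohort.csv"))
      co
    }
  })
  note_stage("load", seed_sim, out("cohort.csv"))

  # --- filter ----------------------------------------------------------
  flt <- run_stage("filter", filter_complete(cohort))
  write_cohort(flt$retained, out("retained.csv"))
  cmp <- if (nrow(flt$dropped) >= 2L) {
    compare_retained_dropped(flt$retained, flt$dropped)
  } else NULL
  write_json_report(list(retained = nrow(flt$retained),
                         dropped = nrow(flt$dropped),
                         retained_vs_dropped = cmp),
                    out("filter.json"))
  note_stage("filter", NA, c(out("retained.csv"), out("filter.json")))

  # --- norms + scoring -------------------------------------------------
  seed_norms <- derive_seed(cfg$master_seed, "norms")
  norms <- cfg$norms %||% run_stage("norms", {
    build_norms(cfg$sim_config, seed = seed_norms)
  })
  scored <- run_stage("score", score_cohort(flt$retained, bank, norms))
  utils::write.csv(scored, out("scored.csv"), row.names = FALSE, na = "")
  counts <- vapply(0:2, function(k) sum(scored$label == k), integer(1))
  write_json_report(list(class_counts = counts,
                         class_percent = percent_integer(counts),
                         by_sex = cohort_summary_by_sex(scored),
                         by_grade = cohort_summary_by_grade(scored)),
                    out("class_summary.json"))
  note_stage("score", seed_norms, c(out("scored.csv"), out("class_summary.json")))

  # --- reliability -----------------------------------------------------
  if ("reliability" %in% cfg$stages) {
    rel <- run_stage("reliability", reliability_report(flt$retained, bank))
    write_json_report(list(alpha_by_scale = as.list(rel$alpha_by_scale),
                           alpha_if_deleted = as.list(rel$alpha_if_deleted),
                           interitem = rel$interitem),
                      out("reliability.json"))
    note_stage("reliability", NA, out("reliability.json"))
  }

  # --- feature selection ----------------------------------------------
  features <- item_cols()
  if ("select" %in% cfg$stages) {
    seed_sel <- derive_seed(cfg$master_seed, "select")
    sel <- run_stage("select", select_features(scored, alpha = cfg$alpha,
                                               cv_folds = cfg$folds, seed = seed_sel))
    features <- setdiff(features, sel$eliminated)
    write_json_report(list(chisq_p = as.list(sel$chisq_p),
                           spearman_rho = as.list(sel$spearman_rho),
                           spearman_p = as.list(sel$spearman_p),
                           rfe_selected = sel$rfe_selected,
                           rfe_cv_accuracy = sel$rfe_cv_accuracy,
                           eliminated = sel$eliminated, alpha = sel$alpha),
                      out("selection.json"))
    note_stage("select", seed_sel, out("selection.json"))
  }

  # --- augmentation ----------------------------------------------------
  datasets <- list(original = scored)
  if ("augment" %in% cfg$stages) {
    seed_aug <- derive_seed(cfg$master_seed, "augment")
    model <- run_stage("augment", fit_augmentation(flt$retained, bank))
    for (r in cfg$ratios) {
      synth <- run_stage("augment", generate_synthetic(model, ratio = r,
                                                       seed = seed_aug + r, norms = norms))
      hybrid <- make_hybrid(scored, synth)
      fid <- fidelity(flt$retained, synth, model)
      utils::write.csv(as.data.frame(synth), out(sprintf("synthetic_1to%d.csv", r)),
                       row.names = FALSE, na = "")
      utils::write.csv(as.data.frame(hybrid), out(sprintf("hybrid_1to%d.csv", r)),
                       row.names = FALSE, na = "")
      write_json_report(list(mw_p = as.list(fid$mw_p),
                             marginal_tv = as.list(fid$marginal_tv),
                             corr_gap = as.list(fid$corr_gap),
                             n_constant = fid$n_constant),
                        out(sprintf("fidelity_1to%d.json", r)))
      datasets[[sprintf("hybrid_1to%d", r)]] <- hybrid
      note_stage(sprintf("augment_1to%d", r), seed_aug + r,
                 c(out(sprintf("synthetic_1to%d.csv", r)),
                   out(sprintf("hybrid_1to%d.csv", r)),
                   out(sprintf("fidelity_1to%d.json", r))))
    }
  }

  # --- model development and evaluation -------------------------------
  if ("evaluate" %in% cfg$stages) {
    seed_eval <- derive_seed(cfg$master_seed, "evaluate")
    comparisons <- list()
    for (ds_name in names(datasets)) {
      ds <- datasets[[ds_name]]
      X <- as.matrix(as.data.frame(ds)[, features, drop = FALSE])
      y <- ds$label
      fold_scores <- list()
      if (cfg$smote_order == "balance_then_split") {
        warning("SMOTE is applied before the train/test split: synthetic test ",
                "records interpolate training records, so test metrics are ",
                "optimistically biased. Use smote_order = 'split_then_balance' ",
                "for leakage-free estimates.", call. = FALSE)
        bal <- smote_balance(X, y, seed = seed_eval)
        spl <- train_test_split(bal$X, bal$y, seed = seed_eval)
      } else {
        spl <- train_test_split(X, y, seed = seed_eval)
        bal <- smote_balance(spl$X_train, spl$y_train, seed = seed_eval)
        spl$X_train <- bal$X
        spl$y_train <- bal$y
      }
      for (fam in cfg$families) {
        gs <- run_stage("evaluate",
                        grid_search_cv(spl$X_train, spl$y_train, fam,
                                       folds = cfg$folds, seed = seed_eval))
        ev <- evaluate_model(gs$model, spl$X_test, spl$y_test,
                             cv_fold_scores = gs$cv_fold_scores,
                             best_params = gs$best_params)
        fname <- out(sprintf("eval_%s_%s.json", ds_name, fam))
        write_json_report(eval_to_list(ev), fname)
        note_stage(sprintf("evaluate_%s_%s", ds_name, fam), seed_eval, fname)
        fold_scores[[fam]] <- gs$cv_fold_scores
      }
      if (length(fold_scores) >= 2L) {
        prs <- utils::combn(names(fold_scores), 2, simplify = FALSE)
        comparisons[[ds_name]] <- lapply(prs, function(pr) {
          cm <- compare_models(fold_scores[[pr[1]]], fold_scores[[pr[2]]])
          c(list(models = paste(pr, collapse = " vs ")), cm)
        })
      }
    }
    if (length(comparisons)) {
      write_json_report(comparisons, out("comparisons.json"))
      note_stage("compare", seed_eval, out("comparisons.json"))
    }
  }

  write_json_report(manifest, out("manifest.json"))
  invisible(manifest)
}
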