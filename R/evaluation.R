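# Evaluation layer: bipartition error rates against the model tree,
# sum-distances to the source-tree profile, experiment orchestration
# across model conditions, and the rank-correlation study relating
# distance-to-source-trees criteria to true error rates.

#' Bipartition error rates of a supertree against the true tree
#'
#' False negative rate: fraction of the true tree's non-trivial
#' bipartitions missing from the estimated tree. False positive rate:
#' fraction of the estimated tree's non-trivial bipartitions absent from
#' the true tree (0 by convention when the estimated tree has no internal
#' edges, so fully unresolved trees are maximally conservative rather than
#' undefined). The Robinson-Foulds rate is the mean of the two.
#'
#' @param tree Estimated tree (`phylo`).
#' @param true_tree True/model tree (`phylo`) on the same leaf set.
#' @return Named numeric vector `c(fn, fp, rf)`, all in `[0, 1]`.
#' @export
error_rates <- function(tree, true_tree) {
  lt <- sort(leaf_set(tree)); l0 <- sort(leaf_set(true_tree))
  if (!identical(lt, l0))
    stopf("leaf sets differ (tree: %d labels, true tree: %d; e.g. %s)",
          length(lt), length(l0),
          paste(utils::head(c(setdiff(lt, l0), setdiff(l0, lt)), 3),
                collapse = ", "))
  b <- bipartition_set(tree); b0 <- bipartition_set(true_tree)
  if (!length(b0)) stopf("true tree has no internal edges")
  fn <- length(setdiff(b0, b)) / length(b0)
  fp <- if (length(b)) length(setdiff(b, b0)) / length(b) else 0
  c(fn = fn, fp = fp, rf = (fn + fp) / 2)
}

#' Sum-distance of a supertree to a source-tree profile
#'
#' The supertree is restricted to each source tree's leaf set and the
#' bipartition distances are accumulated: Sum-FN is the total number of
#' source-tree bipartitions missing from the restricted supertree divided
#' by the total number of source-tree internal edges; Sum-FP is the total
#' number of restricted-supertree bipartitions absent from the source tree
#' divided by the total number of restricted-supertree internal edges (0
#' if that total is 0); Sum-RF is their mean. `aggregate =
#' "mean-of-ratios"` instead averages the per-tree rates (per-tree FP is 0
#' when the restricted supertree has no internal edges).
#'
#' @param tree Supertree (`phylo`) whose leaves cover every source tree.
#' @param profile A [source_tree_profile()] or list of `phylo` trees.
#' @param kind `"fn"`, `"fp"` or `"rf"`.
#' @param aggregate `"ratio-of-sums"` (default) or `"mean-of-ratios"`.
#' @return A rate in `[0, 1]`.
#' @export
sum_distance <- function(tree, profile, kind = c("fn", "fp", "rf"),
                         aggregate = c("ratio-of-sums", "mean-of-ratios")) {
  kind <- match.arg(kind)
  aggregate <- match.arg(aggregate)
  trees <- if (inherits(profile, "source_tree_profile")) profile$trees
           else profile
  if (!length(trees)) stopf("profile is empty")
  sup <- leaf_set(tree)
  fn_num <- fp_num <- fn_den <- fp_den <- numeric(length(trees))
  for (i in seq_along(trees)) {
    t_i <- trees[[i]]
    missing <- setdiff(leaf_set(t_i), sup)
    if (length(missing))
      stopf("source tree %d has taxa not in the supertree: %s", i,
            paste(utils::head(missing, 5), collapse = ", "))
    bt <- bipartition_set(t_i)
    br <- bipartition_set(restrict(tree, leaf_set(t_i)))
    fn_num[i] <- length(setdiff(bt, br)); fn_den[i] <- length(bt)
    fp_num[i] <- length(setdiff(br, bt)); fp_den[i] <- length(br)
  }
  rate <- function(num, den) {
    if (aggregate == "ratio-of-sums") {
      if (sum(den) == 0) 0 else sum(num) / sum(den)
    } else {
      mean(ifelse(den == 0, 0, num / den))
    }
  }
  switch(kind,
         fn = rate(fn_num, fn_den),
         fp = rate(fp_num, fp_den),
         rf = (rate(fn_num, fn_den) + rate(fp_num, fp_den)) / 2)
}

#' Spearman rank correlation with mid-rank ties
#'
#' @param x,y Numeric vectors of equal length `>= 2`.
#' @return The rank correlation in `[-1, 1]`, or `NA` with attribute
#'   `degenerate = TRUE` when either vector has zero rank variance
#'   (undefined correlation; callers exclude these from means).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2) stopf("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stopf("missing values not allowed")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    return(structure(NA_real_, degenerate = TRUE))
  stats::cor(x, y, method = "spearman")
}

# ---- supertree method registry ------------------------------------------

method_registry <- function() {
  qmc <- function(strategy) {
    function(profile, seed = NULL, lambda = 1000, restarts = 10, ...) {
      q <- encode_profile(profile, strategy, seed = derive_seed(seed %||% 0, 1))
      tr <- maxcut_amalgamate(q, taxa = profile_taxa(profile),
                              lambda = lambda, restarts = restarts,
                              seed = derive_seed(seed %||% 0, 2))
      attr(tr, "quartets") <- q
      tr
    }
  }
  list(
    "gmrp" = function(profile, seed = NULL, ...) gmrp(profile, seed = seed, ...),
    "qmc-all" = qmc("all"),
    "qmc-geo-tsq" = qmc("geo+tsq"),
    "qmc-exp-tsq" = qmc("exp+tsq"))
}

#' Names of the registered supertree methods
#' @return Character vector.
#' @export
list_methods <- function() names(method_registry())

#' Run one registered supertree method on a profile
#'
#' @param profile A [source_tree_profile()].
#' @param method One of [list_methods()].
#' @param seed Integer seed.
#' @param ... Passed to the method (e.g. `lambda`, `restarts` for the
#'   QMC-style methods; `iterations`, `starts` for gMRP).
#' @return An unrooted `phylo` supertree on [profile_taxa()].
#' @export
build_supertree <- function(profile, method, seed = NULL, ...) {
  reg <- method_registry()
  if (!method %in% names(reg))
    stopf("unknown method '%s'; registered: %s", method,
          paste(names(reg), collapse = ", "))
  tr <- reg[[method]](profile, seed = seed, ...)
  out <- unroot_tree(tr)
  for (a in c("quartets", "n_dropped", "score"))
    if (!is.null(attr(tr, a))) attr(out, a) <- attr(tr, a)
  out
}

# ---- experiment orchestration -------------------------------------------

#' Run a benchmarking experiment across model conditions
#'
#' For each condition and replicate: build a simulated profile, run every
#' requested method, and score it six ways — FN/FP/RF against the model
#' tree restricted to the profile's taxa, and Sum-FN/FP/RF against the
#' source trees. A method error marks the replicate `failed`; failed
#' replicates stay in the table but are excluded from the per-condition
#' summary, so means always compare the same datasets across methods.
#'
#' @param conditions A [model_condition()] or list of them.
#' @param methods Character vector of registered method names.
#' @param seed Integer master seed; every replicate's randomness is
#'   derived from it.
#' @param method_args Named list (per method name) of extra arguments.
#' @return Data frame with columns `condition`, `density`, `profile_type`,
#'   `replicate`, `method`, `fn`, `fp`, `rf`, `sum_fn`, `sum_fp`,
#'   `sum_rf`, `failed`; attribute `summary` holds
#'   [summarize_experiment()] of the table and `failures` the per-failure
#'   messages.
#' @export
run_experiment <- function(conditions, methods = c("gmrp", "qmc-exp-tsq"),
                           seed = NULL, method_args = list()) {
  if (inherits(conditions, "model_condition")) conditions <- list(conditions)
  reg <- method_registry()
  bad <- setdiff(methods, names(reg))
  if (length(bad))
    stopf("unknown method(s): %s; registered: %s",
          paste(bad, collapse = ", "), paste(names(reg), collapse = ", "))
  seed <- seed %||% 0
  rows <- list(); failures <- character(0)
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    for (r in seq_len(cond$replicates)) {
      rep_seed <- derive_seed(seed, ci * 1000L + r)
      bp <- build_profile(cond, seed = rep_seed)
      taxa <- profile_taxa(bp$profile)
      t0 <- unroot_tree(restrict(bp$model_tree, taxa))
      for (m in methods) {
        args <- c(list(bp$profile, method = m,
                       seed = derive_seed(rep_seed, match(m, names(reg)))),
                  method_args[[m]])
        tr <- tryCatch(do.call(build_supertree, args), error = function(e) e)
        if (inherits(tr, "error")) {
          failures <- c(failures, sprintf("%s rep %d %s: %s",
                        condition_id(cond), r, m, conditionMessage(tr)))
          rows[[length(rows) + 1]] <- data.frame(
            condition = condition_id(cond),
            density = cond$scaffold_density,
            profile_type = cond$profile_type, replicate = r, method = m,
            fn = NA_real_, fp = NA_real_, rf = NA_real_,
            sum_fn = NA_real_, sum_fp = NA_real_, sum_rf = NA_real_,
            failed = TRUE, stringsAsFactors = FALSE)
          next
        }
        er <- error_rates(tr, t0)
        rows[[length(rows) + 1]] <- data.frame(
          condition = condition_id(cond), density = cond$scaffold_density,
          profile_type = cond$profile_type, replicate = r, method = m,
          fn = er[["fn"]], fp = er[["fp"]], rf = er[["rf"]],
          sum_fn = sum_distance(tr, bp$profile, "fn"),
          sum_fp = sum_distance(tr, bp$profile, "fp"),
          sum_rf = sum_distance(tr, bp$profile, "rf"),
          failed = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, summary = summarize_experiment(out), failures = failures)
}

complete_replicates <- function(results) {
  failed_key <- unique(paste(results$condition, results$replicate)[
    results$failed])
  results[!(paste(results$condition, results$replicate) %in% failed_key), ,
          drop = FALSE]
}

#' Per-condition means and standard errors of an experiment table
#'
#' Replicates on which any method failed are excluded entirely (so every
#' method is averaged over the same replicates within a condition).
#'
#' @param results A [run_experiment()] table.
#' @return Data frame: one row per condition x method with `n_replicates`
#'   and `mean_`/`se_` columns for each of the six rates.
#' @export
summarize_experiment <- function(results) {
  ok <- complete_replicates(results)
  metrics <- c("fn", "fp", "rf", "sum_fn", "sum_fp", "sum_rf")
  keys <- unique(ok[, c("condition", "density", "profile_type", "method")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- ok$condition == keys$condition[i] & ok$method == keys$method[i]
    sub <- ok[sel, , drop = FALSE]
    stats_row <- keys[i, , drop = FALSE]
    stats_row$n_replicates <- nrow(sub)
    for (m in metrics) {
      stats_row[[paste0("mean_", m)]] <- mean(sub[[m]])
      stats_row[[paste0("se_", m)]] <-
        if (nrow(sub) > 1) stats::sd(sub[[m]]) / sqrt(nrow(sub)) else NA_real_
    }
    stats_row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank-correlation study: sum-distances vs true error rates
#'
#' Within each complete replicate the methods are ranked by each
#' sum-distance criterion (Sum-FN/FP/RF, the quantities computable without
#' the true tree) and by each true error rate (FN/FP/RF); the Spearman
#' correlation of the two rankings is computed for every criterion x error
#' pair and summarized per scaffold density as mean and range across
#' replicates. Degenerate replicates (all methods tied on either side) are
#' flagged and excluded from the mean.
#'
#' @param results A [run_experiment()] table with `>= 2` methods.
#' @return Data frame: `density` x `criterion` x `error` with `mean_rho`,
#'   `min_rho`, `max_rho`, `n_replicates` (contributing) and `n_degenerate`
#'   (flagged); attribute `per_replicate` holds the underlying per-replicate
#'   rho table.
#' @export
correlation_study <- function(results) {
  ok <- complete_replicates(results)
  if (length(unique(ok$method)) < 2)
    stopf("need results for at least 2 methods")
  criteria <- c("sum_fn", "sum_fp", "sum_rf")
  errors <- c("fn", "fp", "rf")
  reps <- unique(ok[, c("condition", "density", "replicate")])
  per <- list()
  for (i in seq_len(nrow(reps))) {
    sub <- ok[ok$condition == reps$condition[i] &
              ok$replicate == reps$replicate[i], , drop = FALSE]
    if (nrow(sub) < 2) next
    for (cr in criteria) for (er in errors) {
      rho <- spearman_rho(sub[[cr]], sub[[er]])
      per[[length(per) + 1]] <- data.frame(
        condition = reps$condition[i], density = reps$density[i],
        replicate = reps$replicate[i], criterion = cr, error = er,
        rho = as.numeric(rho),
        degenerate = isTRUE(attr(rho, "degenerate")),
        stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  keys <- unique(per[, c("density", "criterion", "error")])
  keys <- keys[order(keys$density, keys$criterion, keys$error), ,
               drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- per$density == keys$density[i] &
           per$criterion == keys$criterion[i] & per$error == keys$error[i]
    sub <- per[sel, , drop = FALSE]
    good <- sub$rho[!sub$degenerate]
    data.frame(density = keys$density[i], criterion = keys$criterion[i],
               error = keys$error[i],
               mean_rho = if (length(good)) mean(good) else NA_real_,
               min_rho = if (length(good)) min(good) else NA_real_,
               max_rho = if (length(good)) max(good) else NA_real_,
               n_replicates = length(good),
               n_degenerate = sum(sub$degenerate),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_replicate = per)
}

#' Write / read experiment and correlation tables as CSV
#'
#' @param results Data frame ([run_experiment()] or [correlation_study()]
#'   output).
#' @param path File path.
#' @return `path` (write) or the data frame (read), invisibly for writes.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  out <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stopf("malformed CSV %s: %s", path, conditionMessage(e)))
  out
}
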