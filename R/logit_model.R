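## The binary logistic model of per-CpG mutation probability:
##
##   log(Pmut / (1 - Pmut)) = b0 + b1*M + b2*M^2 + b3*R + b4*(M x R)
##
## with M = methylation fraction (uncentred, on [0,1]), R = replication
## timing on its native scale. Includes nested-model selection by
## likelihood-ratio test and AIC, in-sample AUC, and the vertex of the
## log-odds quadratic in M at a reference timing.

MODEL_TERMS <- c("M", "M2", "R", "MxR")

#' Specify a nested logistic model
#'
#' The intercept is always included. Term hierarchy is enforced: `M2`
#' requires `M`, and `MxR` requires both `M` and `R`.
#'
#' @param terms Character subset of `c("M", "M2", "R", "MxR")`.
#' @return A `model_spec`.
#' @export
model_spec <- function(terms = MODEL_TERMS) {
  terms <- unique(terms)
  bad <- setdiff(terms, MODEL_TERMS)
  if (length(bad)) stopf("unknown model term(s): %s", paste(bad, collapse = ","))
  if ("M2" %in% terms && !"M" %in% terms) stopf("M2 requires M")
  if ("MxR" %in% terms && !all(c("M", "R") %in% terms)) {
    stopf("MxR requires M and R")
  }
  structure(list(terms = terms), class = "model_spec")
}

#' The default nested specification chain
#'
#' Intercept-only, then adding methylation, its quadratic, replication
#' timing, and the methylation-by-timing interaction, in that order.
#'
#' @return List of `model_spec`, strictly nested.
#' @export
default_spec_chain <- function() {
  list(model_spec(character()),
       model_spec("M"),
       model_spec(c("M", "M2")),
       model_spec(c("M", "M2", "R")),
       model_spec(c("M", "M2", "R", "MxR")))
}

spec_label <- function(spec) {
  if (!length(spec$terms)) "intercept" else paste(spec$terms, collapse = "+")
}

spec_formula <- function(spec) {
  rhs <- c("1",
           if ("M" %in% spec$terms) "M",
           if ("M2" %in% spec$terms) "I(M^2)",
           if ("R" %in% spec$terms) "R",
           if ("MxR" %in% spec$terms) "I(M * R)")
  stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
}

## glm term name -> coefficient symbol
TERM_TO_B <- c("(Intercept)" = "b0", "M" = "b1", "I(M^2)" = "b2",
               "R" = "b3", "I(M * R)" = "b4")

#' Fit the logistic mutation-probability model
#'
#' Maximum-likelihood fit of the binary outcome `mutated` on methylation
#' and replication timing under a [model_spec()]. Convergence tolerance is
#' 1e-8 on the deviance with at most 100 iterations. Sites with missing
#' covariates are dropped.
#'
#' @param table A `cpg_table` (or any data.frame with columns `M`, `R`,
#'   `mutated`).
#' @param spec A `model_spec` (default: the full model).
#' @return A `logistic_fit`: coefficients `b0..b4` (`NA` where absent),
#'   standard errors, `log_lik`, `aic`, `auc` (in-sample), `n`, `r_mean`
#'   (mean timing of the fitted data), `vertex` (at `r_mean`, `NA` when
#'   `b2` is absent), `converged`, and the underlying `glm`.
#' @export
fit_mutation_model <- function(table, spec = model_spec()) {
  tab <- as.data.table(table)
  needs_r <- any(c("R", "MxR") %in% spec$terms)
  df <- data.frame(y = as.integer(tab$mutated), M = tab$M,
                   R = if ("R" %in% names(tab)) tab$R else NA_real_)
  keep <- !is.na(df$y) & !is.na(df$M) & (!needs_r | !is.na(df$R))
  df <- df[keep, , drop = FALSE]
  if (length(unique(df$y)) < 2) {
    stopf("outcome has a single class; model undefined")
  }
  fit <- suppressWarnings(
    glm(spec_formula(spec), family = binomial(), data = df,
        control = glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- fitted(fit)
  if (min(mu[df$y == 1]) > max(mu[df$y == 0]) ||
      all(abs(mu - df$y) < 1e-8)) {
    z <- abs(coef(fit)) / sqrt(diag(vcov(fit)))
    worst <- names(which.max(abs(coef(fit))[names(z)]))
    stopf("complete separation of the outcome (term %s)",
          TERM_TO_B[[worst]] %||% worst)
  }
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  b <- setNames(rep(NA_real_, 5), paste0("b", 0:4))
  bse <- b
  b[TERM_TO_B[names(co)]] <- unname(co)
  bse[TERM_TO_B[names(se)]] <- unname(se)
  r_mean <- if (all(is.na(df$R))) NA_real_ else mean(df$R, na.rm = TRUE)
  out <- structure(list(
    coefficients = b, se = bse, spec = spec,
    log_lik = as.numeric(logLik(fit)), aic = AIC(fit),
    n = nrow(df), n_mutated = sum(df$y),
    auc = auc_score(mu, df$y), r_mean = r_mean,
    converged = fit$converged, glm = fit), class = "logistic_fit")
  out$vertex <- tryCatch(model_vertex(out), error = function(e) NA_real_)
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic mutation-probability model:",
      equation_string(x), "\n")
  cat(sprintf("  n = %d (%d mutated)  logLik = %.2f  AIC = %.2f  AUC = %.4f\n",
              x$n, x$n_mutated, x$log_lik, x$aic, x$auc))
  if (!is.na(x$vertex)) {
    cat(sprintf("  vertex = %.3f at mean timing %.3g\n", x$vertex, x$r_mean))
  }
  invisible(x)
}

#' Render a fitted model as an equation string
#'
#' @param fit A `logistic_fit`.
#' @param digits Significant digits.
#' @return Character scalar, e.g.
#'   `"log(P/(1-P)) = -8.1 + 3.2*M - 1.1*M^2 + 0.01*R + 0.005*M*R"`.
#' @export
equation_string <- function(fit, digits = 4) {
  b <- fit$coefficients
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  parts <- c(fmt(b["b0"]),
             if (!is.na(b["b1"])) paste0(fmt(b["b1"]), "*M"),
             if (!is.na(b["b2"])) paste0(fmt(b["b2"]), "*M^2"),
             if (!is.na(b["b3"])) paste0(fmt(b["b3"]), "*R"),
             if (!is.na(b["b4"])) paste0(fmt(b["b4"]), "*M*R"))
  paste("log(P/(1-P)) =", paste(parts, collapse = " + "))
}

#' Area under the ROC curve by rank statistic
#'
#' The probability that a randomly chosen positive scores above a randomly
#' chosen negative, counting ties as one half (equivalent to the
#' Mann-Whitney statistic). With `orient = TRUE` the larger of `a` and
#' `1 - a` is returned, so the value lies in `[0.5, 1]`.
#'
#' @param scores Numeric scores (e.g. fitted probabilities).
#' @param labels Binary outcomes (0/1 or logical).
#' @param orient Orient the AUC above 0.5 (default `TRUE`).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, orient = TRUE) {
  y <- as.integer(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0L, 1L)))
  n1 <- as.numeric(sum(y == 1L)); n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) stopf("AUC undefined: one class absent")
  r <- rank(scores)
  a <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orient) max(a, 1 - a) else a
}

#' In-sample or new-data AUC of a fitted model
#'
#' @param fit A `logistic_fit`.
#' @param table Optional `cpg_table` to evaluate on; default in-sample.
#' @return AUC.
#' @export
model_auc <- function(fit, table = NULL) {
  if (is.null(table)) return(fit$auc)
  tab <- as.data.table(table)
  df <- data.frame(M = tab$M, R = tab$R)
  mu <- predict(fit$glm, newdata = df, type = "response")
  auc_score(mu, as.integer(tab$mutated))
}

#' Vertex of the log-odds quadratic in methylation
#'
#' At a reference replication timing `r_ref` the log-odds are quadratic in
#' M; the extremum lies at `-(b1 + b4*r_ref) / (2*b2)`. Values outside
#' `[0,1]` are meaningful (a vertex above 1 means the association is
#' monotone increasing over the whole methylation range).
#'
#' @param fit A `logistic_fit` with `b2` estimated and non-zero.
#' @param r_ref Reference timing; default the mean timing of the fitted
#'   data (0 when the model has no timing terms).
#' @return Methylation fraction at the vertex.
#' @export
model_vertex <- function(fit, r_ref = NULL) {
  b <- fit$coefficients
  if (is.na(b["b2"]) || b["b2"] == 0) stopf("no vertex: b2 absent or zero")
  r_ref <- r_ref %||% (if (is.na(fit$r_mean)) 0 else fit$r_mean)
  b4 <- if (is.na(b["b4"])) 0 else b["b4"]
  unname(-(b["b1"] + b4 * r_ref) / (2 * b["b2"]))
}

#' Nested model selection by likelihood-ratio test and AIC
#'
#' Fits a strictly nested chain of specifications, performs the LRT at
#' every consecutive step (statistic `2 * delta logLik`, chi-square with
#' `delta k` degrees of freedom, via `lmtest::lrtest`), and compares AICs.
#' The LRT choice is the largest model reached while every step improves
#' at `p < alpha`; the AIC choice is the smallest-AIC model. When the two
#' disagree this is reported explicitly and the simpler of the two choices
#' is returned as `chosen`.
#'
#' @param table A `cpg_table`.
#' @param specs List of `model_spec`, strictly nested (default
#'   [default_spec_chain()]).
#' @param alpha LRT significance level (default 0.05).
#' @return A `model_selection` list: `fits`, `steps` (`data.table` of per-
#'   step LRT statistics and p-values), `aic` vector, `chosen_lrt`,
#'   `chosen_aic`, `agreement`, `chosen`.
#' @export
select_model <- function(table, specs = default_spec_chain(), alpha = 0.05) {
  stopifnot(length(specs) >= 2)
  for (i in 2:length(specs)) {
    a <- specs[[i - 1]]$terms; b <- specs[[i]]$terms
    if (!all(a %in% b) || length(b) <= length(a)) {
      stopf("specs are not strictly nested at step %d", i)
    }
  }
  fits <- lapply(specs, function(s) fit_mutation_model(table, s))
  labels <- vapply(specs, spec_label, "")
  steps <- data.table::rbindlist(lapply(2:length(fits), function(i) {
    lr <- lmtest::lrtest(fits[[i - 1]]$glm, fits[[i]]$glm)
    data.table(step = labels[i],
               df = lr$Df[2],
               statistic = lr$Chisq[2],
               p_value = lr$`Pr(>Chisq)`[2])
  }))
  pass <- steps$p_value < alpha
  chosen_lrt <- if (all(pass)) length(fits) else which(!pass)[1]
  aics <- vapply(fits, `[[`, 0, "aic")
  chosen_aic <- which.min(aics)
  agreement <- chosen_lrt == chosen_aic
  chosen <- min(chosen_lrt, chosen_aic)
  structure(list(fits = setNames(fits, labels), steps = steps[],
                 aic = setNames(aics, labels),
                 chosen_lrt = labels[chosen_lrt],
                 chosen_aic = labels[chosen_aic],
                 agreement = agreement, chosen = labels[chosen],
                 alpha = alpha),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Nested logistic model selection\n")
  print(x$steps)
  cat(sprintf("  LRT choice: %s  AIC choice: %s%s\n",
              x$chosen_lrt, x$chosen_aic,
              if (x$agreement) "" else "  (criteria disagree)"))
  invisible(x)
}

#' Per-sample vertex distribution
#'
#' Refits the model on each sample's own binary outcome (mutated in that
#' sample or not) and records the vertex at the cohort mean timing.
#' Two groups of per-sample vertices can be compared with an unpaired
#' t-test via [compare_vertex_groups()].
#'
#' @param table A `cpg_table` with `sample_hits`.
#' @param samples Samples to refit (default all with hits).
#' @param spec Model specification (default full).
#' @param r_ref Reference timing for the vertex (default cohort mean).
#' @return `data.table`: `sample_id`, `vertex`, `n_mutated`.
#' @export
per_sample_vertices <- function(table, samples = NULL, spec = model_spec(),
                                r_ref = NULL) {
  hits <- attr(table, "sample_hits")
  if (is.null(hits)) stopf("table lacks per-sample hit information")
  samples <- samples %||% sort(unique(hits$sample_id))
  tab <- as.data.table(table)
  r_ref <- r_ref %||% mean(tab$R, na.rm = TRUE)
  data.table::rbindlist(lapply(samples, function(s) {
    h <- hits[sample_id == s, .(chrom, pos, n)]
    t2 <- h[tab, on = c("chrom", "pos")]
    t2[, mutated := !is.na(n) & n >= 1L]
    v <- tryCatch({
      f <- fit_mutation_model(t2, spec)
      model_vertex(f, r_ref = r_ref)
    }, error = function(e) NA_real_)
    data.table(sample_id = s, vertex = v, n_mutated = t2[, sum(mutated)])
  }))
}

#' Unpaired t-test between two groups of per-sample vertices
#'
#' @param v1,v2 Numeric vectors of vertices (NAs dropped).
#' @return `htest` from [stats::t.test()].
#' @export
compare_vertex_groups <- function(v1, v2) {
  t.test(v1[!is.na(v1)], v2[!is.na(v2)], paired = FALSE)
}

#' Cohort summary table of nested-model results
#'
#' One row per cohort with the fitted full-model equation, vertex at mean
#' timing, full-model AUC, and the AUC gains from adding replication
#' timing (full vs methylation-only) and from adding methylation (full vs
#' timing-only), in percentage points.
#'
#' @param tables Named list of `cpg_table`, one per cohort.
#' @return `data.table` with one row per cohort.
#' @export
cohort_report <- function(tables) {
  data.table::rbindlist(lapply(names(tables), function(g) {
    tab <- tables[[g]]
    full <- fit_mutation_model(tab, model_spec())
    m_only <- fit_mutation_model(tab, model_spec(c("M", "M2")))
    r_only <- fit_mutation_model(tab, model_spec("R"))
    data.table(cohort = g, equation = equation_string(full),
               vertex = full$vertex, auc = full$auc,
               auc_gain_timing_pct = 100 * (full$auc - m_only$auc),
               auc_gain_methylation_pct = 100 * (full$auc - r_only$auc),
               n = full$n, n_mutated = full$n_mutated)
  }))
}
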