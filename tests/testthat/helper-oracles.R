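## Independent oracles, kept deliberately naive and separate from the
## implementation paths they check.

## Log-likelihood of the logistic model written out directly.
oracle_loglik <- function(b, M, R, y) {
  lp <- b[1] + b[2] * M + b[3] * M^2 + b[4] * R + b[5] * (M * R)
  sum(y * lp - log1p(exp(lp)))
}

## Maximum-likelihood coefficients by general-purpose numerical
## optimisation of the written likelihood (BFGS from several starts).
oracle_fit <- function(M, R, y) {
  nll <- function(b) -oracle_loglik(b, M, R, y)
  best <- NULL
  for (start in list(rep(0, 5), c(-2, 1, -1, 0, 0))) {
    o <- optim(start, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ## polish with straight Newton steps on the written score / Hessian
  X <- cbind(1, M, M^2, R, M * R)
  b <- best$par
  for (i in 1:50) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    score <- drop(crossprod(X, y - p))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    b <- b + step
    if (max(abs(step)) < 1e-12) break
  }
  if (oracle_loglik(b, M, R, y) < -best$value) b <- best$par
  b <- unname(b)
  list(coefficients = b, log_lik = oracle_loglik(b, M, R, y))
}

## AUC by exhaustive pairwise comparison, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

## Two-sided Fisher exact p for a 2x2 table by full hypergeometric
## enumeration: sum the probabilities of all tables with the same margins
## whose point probability does not exceed the observed one (with the
## conventional 1 + 1e-7 relative tolerance).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # first row total
  k <- a + c          # first column total
  n <- a + b + c + d
  support <- max(0, k + m - n):min(k, m)
  probs <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n - m, k - x) - lchoose(n, k))
  }, 0)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Stop-gain scan by brute force: generate every single-base substitution
## of the CDS, translate the whole mutant sequence, and keep substitutions
## that are a C>T on either strand in a TCG context and put a stop codon
## exactly at the mutated codon (where the reference had none).
oracle_stop_gain <- function(cds, flank5 = "N", flank3 = "N") {
  b <- strsplit(toupper(cds), "")[[1]]
  L <- length(b)
  ref_prot <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(cds),
                          if.fuzzy.codon = "X")), "")[[1]]
  up <- c(toupper(flank5), b[-L])
  down <- c(b[-1], toupper(flank3))
  out <- list()
  for (i in seq_len(L)) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[i])) {
      coding_ct <- b[i] == "C" && alt == "T" &&
        up[i] == "T" && down[i] == "G"
      template_ct <- b[i] == "G" && alt == "A" &&
        up[i] == "C" && down[i] == "A"
      if (!coding_ct && !template_ct) next
      mut <- b
      mut[i] <- alt
      prot <- strsplit(as.character(
        Biostrings::translate(Biostrings::DNAString(paste(mut, collapse = "")),
                              if.fuzzy.codon = "X")), "")[[1]]
      ci <- (i - 1) %/% 3 + 1
      if (prot[ci] == "*" && ref_prot[ci] != "*") {
        out[[length(out) + 1]] <- data.frame(
          cds_pos = i, strand = if (coding_ct) "coding" else "template")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cds_pos = integer(), strand = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$cds_pos, res$strand), , drop = FALSE]
}

## Random in-frame CDS of the given codon count.
random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}

## Minimal binned-association stub for slope-comparison tests.
make_assoc <- function(mids, rates, n_cpg = 100L) {
  structure(list(bins = data.table::data.table(
    mid = mids, n_cpg = n_cpg, events = 0L, rate = rates),
    slope = NA, intercept = NA, r_squared = NA, p_value = NA,
    bin_width = diff(mids[1:2]), measure = "events",
    n_sites = sum(n_cpg)), class = "binned_assoc")
}
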