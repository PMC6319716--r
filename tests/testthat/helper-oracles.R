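# Independent reference implementations used to cross-check the package.
# Deliberately written as literal loops over the stated rules, sharing no
# code with the implementation under test.

# Gene-level CNV caller: plain-R enumeration of exons applying the
# duplication/deletion thresholds literally.
brute_force_cnv <- function(study, control, model,
                            dup_ratio = 1.5, del_ratio = 0.5,
                            exon_fraction = 0.70, pseudocount = 0.5) {
  s <- study$depth + pseudocount
  ctl <- control$depth + pseudocount
  masked <- study$depth == 0 & control$depth == 0
  s_norm <- s / median(s[!masked])
  c_norm <- ctl / median(ctl[!masked])
  out <- list()
  for (g in unique(model$gene_id)) {
    idx <- which(model$gene_id == g & !masked)
    if (length(idx) == 0) next
    ref <- median(c_norm[idx])
    gain_frac <- sum(s_norm[idx] > dup_ratio * ref) / length(idx)
    loss_frac <- sum(s_norm[idx] < del_ratio * ref) / length(idx)
    call <- NULL
    if (gain_frac > exon_fraction && loss_frac > exon_fraction) {
      if (gain_frac > loss_frac) call <- "gain"
      if (loss_frac > gain_frac) call <- "loss"
    } else if (gain_frac > exon_fraction) {
      call <- "gain"
    } else if (loss_frac > exon_fraction) {
      call <- "loss"
    }
    if (!is.null(call)) {
      out[[g]] <- data.frame(
        gene_id = g, call = call,
        supporting_exon_fraction = if (call == "gain") gain_frac else loss_frac,
        mean_log2_ratio = mean(log2(s_norm[idx] / c_norm[idx]))
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), call = character(),
                      supporting_exon_fraction = numeric(),
                      mean_log2_ratio = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id), , drop = FALSE]
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mwu_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(combn(nx + ny, nx), 2, u_of)
  p_le <- mean(all_u <= u_obs)
  p_ge <- mean(all_u >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Friedman statistic from first principles: within-block midranks, the
# classic chi-square form, divided by the standard tie-correction factor.
friedman_brute <- function(m) {
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  stat <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  tie_term <- 0
  for (i in seq_len(n)) {
    t_sizes <- table(m[i, ])
    tie_term <- tie_term + sum(t_sizes^3 - t_sizes)
  }
  correction <- 1 - tie_term / (n * k * (k^2 - 1))
  stat / correction
}

# Binomial standard error in percentage points, for recovery tolerances.
binom_se_pct <- function(p, n) 100 * sqrt(p * (1 - p) / n)
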