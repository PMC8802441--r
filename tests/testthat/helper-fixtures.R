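# Shared fixtures and independent oracles.

# Minimal pair index: case ids c01..c<n>, reference ids r01..r<n>.
tiny_pairs <- function(n) {
  data.frame(pair_id = sprintf("p%03d", seq_len(n)),
             case = sprintf("c%03d", seq_len(n)),
             reference = sprintf("r%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Score/code matrix with the tiny_pairs row naming.
paired_matrix <- function(case_rows, ref_rows) {
  n <- nrow(case_rows)
  m <- rbind(case_rows, ref_rows)
  rownames(m) <- c(sprintf("c%03d", seq_len(n)), sprintf("r%03d", seq_len(n)))
  m
}

# Fully formed matched patient table for n pairs of one sex.
make_patients <- function(n, sex = "F", seed = 1) {
  local({
    set.seed(seed)
    pair_id <- sprintf("%s%04d", sex, seq_len(n))
    cov <- data.frame(age = round(runif(n, 5, 95), 1),
                      income_quintile = sample(1:5, n, TRUE),
                      rural = runif(n) < 0.15,
                      index_date = as.Date("2010-01-01") + sample(0:2000, n, TRUE))
    rbind(data.frame(patient_id = paste0(pair_id, "C"), pair_id = pair_id,
                     cohort_arm = "case", sex = sex, cov),
          data.frame(patient_id = paste0(pair_id, "R"), pair_id = pair_id,
                     cohort_arm = "reference", sex = sex, cov))
  })
}

# Oracle: discordant counts by an explicit pair loop.
brute_discordant <- function(x, pairs, code) {
  b <- 0L; cc <- 0L
  for (i in seq_len(nrow(pairs))) {
    xc <- x[pairs$case[i], code]
    xr <- x[pairs$reference[i], code]
    if (xc == 1L && xr == 0L) b <- b + 1L
    if (xr == 1L && xc == 0L) cc <- cc + 1L
  }
  list(b = b, c = cc)
}

# Oracle: exact two-sided McNemar p by summing binomial point masses
# computed from first principles (choose(), not pbinom).
brute_exact_p <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  pm <- choose(n, 0:n) * 0.5^n
  min(1, 2 * sum(pm[seq_len(min(b, c) + 1L)]))
}

# Oracle: greedy Ward agglomeration via the Lance-Williams recurrence,
# written independently of hclust; returns successive merge heights and the
# final two-cluster partition sizes.
brute_ward <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  D <- d
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1L) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (D[i, j] < best[1] - 1e-12) best <- c(D[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges[[length(merges) + 1L]] <- list(a = active[[i]], b = active[[j]])
    ni <- sizes[i]; nj <- sizes[j]
    newD <- numeric(k)
    for (l in seq_len(k)) {
      if (l == i || l == j) next
      nl <- sizes[l]
      newD[l] <- ((ni + nl) * D[i, l] + (nj + nl) * D[j, l] -
                    nl * D[i, j]) / (ni + nj + nl)
    }
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- matrix(0, k - 1, k - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[k - 1, seq_along(keep)] <- D2[seq_along(keep), k - 1] <- newD[keep]
    D <- D2
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(heights = heights, merges = merges)
}

# Correlated binary columns through a Gaussian copula (test-side generator,
# independent of the package's simulator).
copula_binaries <- function(n, rho, p = 0.3) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind((z1 > qnorm(1 - p)) * 1L, (z2 > qnorm(1 - p)) * 1L)
}
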