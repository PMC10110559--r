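# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided exact rank-sum p-value for tie-free data from the classical
# Mann-Whitney null distribution (stats::dwilcox), independent of the
# package's enumeration.
oracle_rank_p <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  u_all <- 0:(n1 * n2)
  sum(stats::dwilcox(u_all[abs(u_all - mid) >= abs(u_obs - mid) - 1e-9],
                     n1, n2))
}

# Naive O(n^3) Ward clustering from cluster members and centroids:
# at each step merge the pair minimising sqrt(2 * |A||B|/(|A|+|B|) *
# ||centroid_A - centroid_B||^2), i.e. the Ward.D2 merge height.
oracle_ward_heights <- function(X) {
  cl <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  while (length(cl) > 1) {
    best <- Inf
    bi <- bj <- 0L
    for (i in seq_len(length(cl) - 1)) {
      for (j in seq(i + 1, length(cl))) {
        A <- X[cl[[i]], , drop = FALSE]
        B <- X[cl[[j]], , drop = FALSE]
        d <- sqrt(2 * nrow(A) * nrow(B) / (nrow(A) + nrow(B)) *
                    sum((colMeans(A) - colMeans(B))^2))
        if (d < best) {
          best <- d
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, best)
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl <- cl[-bj]
  }
  heights
}

# Brute-force N/O sulfate-group counter: expands composite labels into
# member codes and reads sulfation positions straight off the code
# characters, splitting the peak amount equally among members.
oracle_no_total <- function(analytes, amounts) {
  n_tot <- 0
  o_tot <- 0
  for (k in seq_along(analytes)) {
    members <- strsplit(gsub(" ", "", analytes[k]), "+", fixed = TRUE)[[1]]
    share <- amounts[k] / length(members)
    for (m in members) {
      chars <- strsplit(m, "")[[1]]
      n_s <- as.integer(chars[3] == "S")
      tail <- paste(chars[-(1:3)], collapse = "")
      o_s <- as.integer(chars[2] == "2") +
        switch(tail, "0" = 0L, "4" = 1L, "6" = 1L, "10" = 2L)
      n_tot <- n_tot + share * n_s
      o_tot <- o_tot + share * o_s
    }
  }
  if (o_tot == 0) NA_real_ else n_tot / o_tot
}

# Random GAG profile over the canonical analyte panels.
random_profile <- function(gag_class = c("CS", "HS"), zero_frac = 0.2) {
  gag_class <- match.arg(gag_class)
  analytes <- default_analytes(gag_class)
  amounts <- stats::rexp(length(analytes), rate = 0.1)
  amounts[stats::runif(length(analytes)) < zero_frac] <- 0
  tibble::tibble(region = "r", analyte = analytes, amount = amounts)
}

# Metadata for a two-group synthetic comparison without patient structure.
two_group_metadata <- function(n_a, n_b, group_b = "solid") {
  tibble::tibble(
    region = paste0("R", seq_len(n_a + n_b)),
    patient = paste0("P", seq_len(n_a + n_b)),
    morphology = c(rep("normal", n_a), rep(group_b, n_b)),
    mucin = NA_integer_,
    stroma = NA_integer_
  )
}
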