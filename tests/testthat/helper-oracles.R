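# Independent brute-force oracles used to verify the package's numerics.
# These deliberately use naive loops / dense grids, not the package's own
# code paths.

# Dense-grid (Riemann midpoint) marginal log-likelihood for a latent-class
# Rasch model with normal traits. X: patients x items with NA; pi, mu,
# sigma length C; beta C x I.
oracle_marginal_loglik <- function(X, pi_c, beta, mu, sigma, a,
                                   npts = 10000, lim = 10) {
    C <- length(pi_c)
    total <- 0
    for (p in seq_len(nrow(X))) {
        x <- X[p, ]
        lik <- 0
        for (c in seq_len(C)) {
            lo <- mu[c] - lim * sigma[c]
            hi <- mu[c] + lim * sigma[c]
            h <- (hi - lo) / npts
            th <- lo + (seq_len(npts) - 0.5) * h
            f <- dnorm(th, mu[c], sigma[c])
            for (i in seq_along(x)) {
                if (is.na(x[i])) next
                pr <- plogis(a * (th - beta[c, i]))
                f <- f * if (x[i] == 1) pr else 1 - pr
            }
            lik <- lik + pi_c[c] * sum(f) * h
        }
        total <- total + log(lik)
    }
    total
}

# Naive cross-tab Loevinger H: returns list(Hpair, Hitem, Hscale) with NA
# for degenerate pairs. More prevalent item of each pair plays the easier
# role; prevalence ties resolved toward the lower column index.
oracle_H <- function(X) {
    I <- ncol(X)
    Fm <- Em <- matrix(NA_real_, I, I)
    for (i in seq_len(I - 1)) for (j in (i + 1):I) {
        ok <- !is.na(X[, i]) & !is.na(X[, j])
        a <- X[ok, i]; b <- X[ok, j]
        n <- length(a)
        if (n == 0) { Fm[i, j] <- Fm[j, i] <- 0; Em[i, j] <- Em[j, i] <- 0; next }
        if (mean(a) >= mean(b)) { easy <- a; hard <- b } else { easy <- b; hard <- a }
        f <- 0
        for (r in seq_len(n)) if (easy[r] == 0 && hard[r] == 1) f <- f + 1
        e <- n * mean(easy == 0) * mean(hard == 1)
        Fm[i, j] <- Fm[j, i] <- f
        Em[i, j] <- Em[j, i] <- e
    }
    Hpair <- ifelse(Em > 0, 1 - Fm / Em, NA_real_)
    Hitem <- numeric(I)
    for (i in seq_len(I)) {
        e <- sum(Em[i, Em[i, ] > 0 & !is.na(Em[i, ])], na.rm = TRUE)
        f <- sum(Fm[i, Em[i, ] > 0 & !is.na(Em[i, ])], na.rm = TRUE)
        Hitem[i] <- if (e > 0) 1 - f / e else NA_real_
    }
    ut <- upper.tri(Em)
    good <- ut & !is.na(Em) & Em > 0
    Hscale <- if (sum(Em[good]) > 0)
        1 - sum(Fm[good]) / sum(Em[good]) else NA_real_
    list(Hpair = Hpair, Hitem = Hitem, Hscale = Hscale)
}

# Naive pair-enumeration Guttman error count for one ordered pattern.
oracle_guttman <- function(x) {
    n <- length(x)
    cnt <- 0
    if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (is.na(x[i]) || is.na(x[j])) next
        if (x[i] == 0 && x[j] == 1) cnt <- cnt + 1
    }
    cnt
}

# Random small response matrix (complete by default).
rand_binary_matrix <- function(n, I, p = NULL, miss = 0) {
    if (is.null(p)) p <- runif(I, 0.2, 0.8)
    X <- sapply(p, function(pp) rbinom(n, 1, pp)) + 0
    if (!is.matrix(X)) X <- matrix(X, nrow = n)
    if (miss > 0) X[matrix(runif(n * I) < miss, n, I)] <- NA
    dimnames(X) <- list(sprintf("P%03d", seq_len(n)),
                        sprintf("c%02d", seq_len(I)))
    X
}

# Align estimated class labels to truth by best permutation; returns the
# achieved assignment accuracy.
best_permutation_accuracy <- function(est, truth, C) {
    perms <- function(v) {
        if (length(v) == 1) return(list(v))
        out <- list()
        for (i in seq_along(v))
            for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
        out
    }
    best <- 0
    for (pm in perms(seq_len(C)))
        best <- max(best, mean(pm[est] == truth))
    best
}

tiny_matrix <- function() {
    DiagnosisMatrix(matrix(
        c(1, 1, 0, NA,
          0, 1, 1, 0,
          1, 0, 0, 1), 3, 4, byrow = TRUE,
        dimnames = list(c("P1", "P2", "P3"),
                        c("htn", "pain", "dm", "chf"))))
}
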