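# exact lasso solution by KKT sign-pattern enumeration: minimizes
# (1/2n)||y - b0 - Xb||^2 + lambda * ||b||_1 with unpenalized intercept
kkt_lasso <- function(X, y, lambda) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  for (A in subsets) {
    k <- length(A)
    signs_list <- if (k == 0) list(numeric(0)) else {
      g <- expand.grid(rep(list(c(-1, 1)), k))
      lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
    }
    for (s in signs_list) {
      b <- numeric(p)
      if (k > 0) {
        XA <- Xc[, A, drop = FALSE]
        bA <- try(solve(crossprod(XA) / n, crossprod(XA, yc) / n - lambda * s),
                  silent = TRUE)
        if (inherits(bA, "try-error")) next
        if (any(sign(bA) != s)) next
        b[A] <- bA
      }
      resid <- yc - Xc %*% b
      grad_inactive <- abs(crossprod(Xc[, setdiff(1:p, A), drop = FALSE], resid)) / n
      if (all(grad_inactive <= lambda + 1e-10)) {
        return(list(b0 = mean(y) - sum(colMeans(X) * b), b = b))
      }
    }
  }
  stop("no KKT-consistent solution found")
}
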