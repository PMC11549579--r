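# The five-message room used throughout: users A and B plus a moderator,
# alternating messages at minutes 1..5.
worked_example_corpus <- function() {
  sessions <- tibble::tibble(
    session_key = "S1",
    user_id = c("A", "B"),
    struggle_text = c("struggle of A", "struggle of B"),
    topic = c("loneliness", "anxiety"),
    device = c("desktop", "mobile")
  )
  transcripts <- tibble::tibble(
    session_key = "S1",
    author_id = c("A", "B", "M", "A", "B"),
    author_role = c("user", "user", "moderator", "user", "user"),
    t_min = 1:5,
    text = c("m1", "m2", "m3", "m4", "m5")
  )
  chat_corpus(sessions, transcripts)
}

# A small synthetic corpus for plumbing tests.
small_sim <- function(seed = 1, n = 12, ...) {
  generate_corpus(generator_config(n_sessions = n, ...), seed = seed)
}

# Independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to the x-sample and count pairwise wins (ties worth 1/2) directly,
# without ranks.
mw_perm_oracle <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n <- length(x)
  N <- length(pooled)
  idx <- utils::combn(N, n)
  Us <- numeric(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    xs <- pooled[idx[, k]]
    ys <- pooled[-idx[, k]]
    Us[k] <- sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  p <- if (alternative == "less") mean(Us <= U_obs + 1e-9) else
    mean(Us >= U_obs - 1e-9)
  list(U = U_obs, p = p)
}

# Unpenalized binomial log-likelihood at coefficients beta (intercept first).
binom_loglik <- function(x, y, beta) {
  eta <- drop(cbind(1, x) %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# Best log-likelihood over a 0.01-step coefficient lattice, found by
# hierarchical refinement (valid because the log-likelihood is concave).
# All candidate points lie on the 0.01 lattice anchored at -10.
grid_loglik_oracle <- function(x, y) {
  x <- as.matrix(x)
  d <- ncol(x) + 1L
  eval_grid <- function(G) {
    best <- -Inf
    best_pt <- NULL
    chunk <- max(1L, floor(2e5 / 1))
    for (s in seq(1, nrow(G), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(G))
      eta <- cbind(1, x) %*% t(G[s:e, , drop = FALSE])
      ll <- colSums(y * eta - log1p(exp(eta)))
      j <- which.max(ll)
      if (ll[j] > best) {
        best <- ll[j]
        best_pt <- G[s + j - 1L, ]
      }
    }
    list(ll = best, pt = best_pt)
  }
  lattice <- function(centers, step, half) {
    axes <- lapply(centers, function(c0) {
      # snap to the global 0.01 lattice
      v <- seq(c0 - half, c0 + half, by = step)
      pmin(pmax(round((v + 10) / 0.01) * 0.01 - 10, -10), 10)
    })
    as.matrix(expand.grid(axes))
  }
  if (d == 2L) {
    coarse <- eval_grid(lattice(c(0, 0), 0.2, 10))
    mid <- eval_grid(lattice(coarse$pt, 0.02, 0.2))
    fine <- eval_grid(lattice(mid$pt, 0.01, 0.02))
  } else if (d == 3L) {
    coarse <- eval_grid(lattice(rep(0, 3), 0.5, 10))
    mid <- eval_grid(lattice(coarse$pt, 0.05, 0.5))
    fine <- eval_grid(lattice(mid$pt, 0.01, 0.05))
  } else {
    coarse <- eval_grid(lattice(rep(0, d), 1, 10))
    mid <- eval_grid(lattice(coarse$pt, 0.1, 1))
    mid2 <- eval_grid(lattice(mid$pt, 0.01, 0.1))
    fine <- mid2
  }
  max(coarse$ll, fine$ll)
}
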