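# Independent brute-force oracles used to validate the fast implementations.

# dense SSA: explicit trajectory matrix, full SVD, per-component
# anti-diagonal means computed by direct index extraction
brute_ssa <- function(x, L, max_components = 30L) {
  n <- length(x)
  K <- n - L + 1L
  X <- matrix(0, L, K)
  for (j in seq_len(K)) X[, j] <- x[j:(j + L - 1L)]
  s <- svd(X)
  r <- min(max_components, sum(s$d > s$d[1L] * 1e-12))
  comps <- matrix(0, n, r)
  for (i in seq_len(r)) {
    Xi <- s$d[i] * outer(s$u[, i], s$v[, i])
    for (t in seq_len(n)) {
      ii <- max(1L, t - K + 1L):min(L, t)
      comps[t, i] <- mean(Xi[cbind(ii, t - ii + 1L)])
    }
  }
  list(d = s$d, components = comps)
}

# exhaustive one-to-one event assignment: maximize pairs, then minimize
# total |offset|; recursion over truth events trying every feasible partner
brute_match <- function(t, d, tol) {
  best <- list(pairs = -1L, cost = Inf)
  m <- length(d)
  recurse <- function(i, used, pairs, cost) {
    if (i > length(t)) {
      if (pairs > best$pairs ||
          (pairs == best$pairs && cost < best$cost)) {
        best <<- list(pairs = pairs, cost = cost)
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, used, pairs, cost)  # leave truth i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && abs(t[i] - d[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, pairs + 1L, cost + abs(t[i] - d[j]))
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L, 0)
  best
}

# per-sample scan of the turn start/end criteria
brute_turn_scan <- function(yaw, rate, start_yaw = 15, start_rate = 30,
                            end_margin = 5) {
  ymax <- max(abs(yaw))
  if (ymax <= start_yaw) return(NULL)
  start <- NA_integer_
  for (i in seq_along(yaw)) {
    if (abs(yaw[i]) > start_yaw && abs(rate[i]) > start_rate) {
      start <- i
      break
    }
  }
  if (is.na(start)) return(NULL)
  end <- NA_integer_
  for (i in start:length(yaw)) {
    if (abs(yaw[i]) >= ymax - end_margin) {
      end <- i
      break
    }
  }
  if (end == start) end <- min(end + 1L, length(yaw))
  list(start = start, end = end)
}

# quick builder for bare trials from channel vectors
make_trial <- function(si, ml = NULL, ap = NULL, gsi = NULL, gml = NULL,
                       gap = NULL, fs = 100) {
  n <- length(si)
  z <- numeric(n)
  imu_trial(cbind(si = si, ml = if (is.null(ml)) z else ml,
                  ap = if (is.null(ap)) z else ap),
            cbind(si = if (is.null(gsi)) z else gsi,
                  ml = if (is.null(gml)) z else gml,
                  ap = if (is.null(gap)) z else gap),
            fs = fs, missing_mask = rep(FALSE, n))
}
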