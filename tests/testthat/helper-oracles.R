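# Independent brute-force oracles used to pin expected kernel values.

# Regular replication by exhaustive enumeration: 2i mutant and 2(n-i)
# wild-type labelled copies, all C(2n, n) assignments of n copies to the
# first daughter. Returns the unordered-pair distribution as data frame.
enum_regular_pairs <- function(n, i) {
  copies <- c(rep(1L, 2L * i), rep(0L, 2L * (n - i)))
  sets <- utils::combn(2L * n, n)
  j <- apply(sets, 2L, function(idx) sum(copies[idx]))
  k <- 2L * i - j
  key <- paste(pmin(j, k), pmax(j, k))
  tab <- table(key) / ncol(sets)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(j = as.integer(parts[, 1L]), k = as.integer(parts[, 2L]),
                    prob = as.numeric(tab))
  out[order(out$j), , drop = FALSE]
}

# Polya urn by dynamic programming over (mutant count, pool size):
# pmf of the mutant count once the pool has grown from n to 2n copies.
dp_polya <- function(n, i) {
  probs <- stats::setNames(1, as.character(i))
  for (tot in n:(2L * n - 1L)) {
    nxt <- numeric(0)
    for (mname in names(probs)) {
      mut <- as.integer(mname)
      p <- probs[[mname]]
      up <- as.character(mut + 1L)
      same <- as.character(mut)
      nxt[up] <- (if (is.na(nxt[up])) 0 else nxt[up]) + p * mut / tot
      nxt[same] <- (if (is.na(nxt[same])) 0 else nxt[same]) +
        p * (tot - mut) / tot
    }
    probs <- nxt[nxt > 0]
  }
  out <- numeric(2L * n + 1L)
  out[as.integer(names(probs)) + 1L] <- probs
  out
}

# Single-mutation law by enumeration: the mutation strikes one of the n
# replication events uniformly (all templates are wild type until then);
# the new copy then amplifies under the urn DP to the 2n-copy pool.
enum_single_mutation <- function(n) {
  pmf <- numeric(2L * n)
  for (r in seq_len(n)) {
    # after the r-th replication there is 1 mutant among n + r copies
    probs <- stats::setNames(1, "1")
    tot0 <- n + r
    if (tot0 < 2L * n) {
      for (tot in tot0:(2L * n - 1L)) {
        nxt <- numeric(0)
        for (mname in names(probs)) {
          mut <- as.integer(mname)
          p <- probs[[mname]]
          up <- as.character(mut + 1L)
          nxt[up] <- (if (is.na(nxt[up])) 0 else nxt[up]) + p * mut / tot
          nxt[mname] <- (if (is.na(nxt[mname])) 0 else nxt[mname]) +
            p * (tot - mut) / tot
        }
        probs <- nxt[nxt > 0]
      }
    }
    for (mname in names(probs)) {
      m <- as.integer(mname)
      pmf[m] <- pmf[m] + probs[[mname]] / n
    }
  }
  pmf[seq_len(n)]
}

# pair-distribution lookup helper
pair_prob <- function(df, j, k) {
  hit <- df$j == min(j, k) & df$k == max(j, k)
  if (any(hit)) sum(df$prob[hit]) else 0
}

dominant4 <- function(s_max = 1.0, s_min = -0.1, n = 4) {
  fitness_model(n, "dominant", s_min = s_min, s_max = s_max)
}
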