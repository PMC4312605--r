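# Independent oracles used across tests. Each re-derives the quantity it
# checks by a different route than the package implementation.

# weighted pair score, duplicated here on purpose (test-side ground truth)
oracle_pair_weight <- function(a, b) {
  if (a == "T") a <- "U"
  if (b == "T") b <- "U"
  if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3L)
  if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(2L)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1L)
  0L
}

# exhaustive enumeration of all nested structures (no memoisation): the
# ground truth for the folding optimum at small n
oracle_fold_score <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i <= min_loop) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      w <- oracle_pair_weight(ch[i], ch[k])
      if (w > 0L) {
        s <- w + (if (k - 1L >= i + 1L) rec(i + 1L, k - 1L) else 0L) +
          (if (k + 1L <= j) rec(k + 1L, j) else 0L)
        if (s > best) best <- s
      }
    }
    best
  }
  rec(1L, length(ch))
}

# Audic-Claverie tail probabilities by direct term-by-term summation using
# the multiplicative recurrence p(y) = p(y-1) f (x+y) / (y (1+f)); no
# log-gamma, unlike the implementation
oracle_ac_test <- function(x, n1, y, n2, tol = 1e-17) {
  f <- n2 / n1
  terms <- numeric(y + 2)
  pk <- (1 + f)^-(x + 1)   # p(0 | x)
  terms[1] <- pk
  k <- 0
  total <- pk
  mode <- (x + 1) * f
  repeat {
    k <- k + 1
    pk <- pk * f * (x + k) / (k * (1 + f))
    terms[k + 1] <- pk
    total <- total + pk
    if (k >= y && k > mode && pk < tol * total) break
    if (k > y + 2e6) break
  }
  lower <- sum(terms[seq_len(y + 1)])               # P(Y <= y)
  upper <- sum(terms[(y + 1):(k + 1)])              # P(Y >= y)
  min(1, 2 * min(min(lower, 1), min(upper, 1)))
}

# negative-binomial identity: the AC conditional of y given x is
# NB(size = x + 1, prob = 1 / (1 + f)); an independent closed-form oracle
oracle_ac_test_nb <- function(x, n1, y, n2) {
  f <- n2 / n1
  prob <- 1 / (1 + f)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

# brute-force enumeration of every alignment with at most one gap
oracle_duplex_pen <- function(a, b, scheme) {
  if (a == "T") a <- "U"
  if (b == "T") b <- "U"
  wc <- (a == "A" && b == "U") || (a == "U" && b == "A") ||
    (a == "G" && b == "C") || (a == "C" && b == "G")
  if (wc) return(0)
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(scheme$wobble)
  scheme$mismatch
}

oracle_pos_mult <- function(pos, scheme) {
  if (pos > scheme$score_len) return(0)
  if (pos >= scheme$seed[1] && pos <= scheme$seed[2]) {
    return(scheme$seed_multiplier)
  }
  1
}

oracle_best_alignment <- function(mirna, site, scheme) {
  mc <- strsplit(gsub("U", "T", toupper(mirna)), "")[[1]]
  sc <- rev(strsplit(gsub("U", "T", toupper(site)), "")[[1]])  # site 3'->5'
  m <- length(mc)
  n <- length(sc)
  score_nogap <- function(mi, si) {
    # mi, si: index vectors of equal length, mi NA = gap in miRNA,
    # si NA = gap in site
    tot <- 0
    mir_pos <- 0
    for (k in seq_along(mi)) {
      if (!is.na(mi[k])) mir_pos <- mir_pos + 1
      pos <- if (is.na(mi[k])) min(mir_pos + 1, m) else mir_pos
      pen <- if (is.na(mi[k]) || is.na(si[k])) {
        scheme$gap
      } else {
        oracle_duplex_pen(mc[mi[k]], sc[si[k]], scheme)
      }
      tot <- tot + pen * oracle_pos_mult(pos, scheme)
    }
    tot
  }
  best <- Inf
  if (m == n) {
    best <- min(best, score_nogap(1:m, 1:n))
  }
  if (n == m + 1) {
    for (g in 0:m) {  # gap in miRNA after consuming g miRNA bases
      mi <- append(1:m, NA, after = g)
      best <- min(best, score_nogap(mi, 1:n))
    }
  }
  if (m == n + 1) {
    for (g in 0:n) {  # gap in site
      si <- append(1:n, NA, after = g)
      best <- min(best, score_nogap(1:m, si))
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
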