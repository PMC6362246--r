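## Independent oracles used across the suite.  Each is a deliberately
## naive re-derivation, kept free of the package's own code paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

## --- six-frame stop-to-stop CDS oracle -------------------------------
## Translates each frame with its own codon table, splits the protein on
## stops, and derives coordinates from segment positions.
oracle_codon_table <- local({
  tab <- as.list(Biostrings::GENETIC_CODE)
  function(codon) {
    if (grepl("N", codon)) return("X")
    tab[[codon]]
  }
})

oracle_cds <- function(s, min_aa) {
  s <- toupper(s)
  L <- nchar(s)
  rows <- list()
  for (strand in c("+", "-")) {
    w <- if (strand == "+") s else rc(s)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod == 0) next
      aa <- character(ncod)
      for (i in seq_len(ncod)) {
        aa[i] <- oracle_codon_table(substr(w, frame + 3 * i - 2,
                                           frame + 3 * i))
      }
      prot <- paste(aa, collapse = "")
      # segment boundaries around '*'
      stop_at <- which(aa == "*")
      bounds_from <- c(1, stop_at + 1)
      bounds_to <- c(stop_at - 1, ncod)
      for (k in seq_along(bounds_from)) {
        from <- bounds_from[k]; to <- bounds_to[k]
        n_aa <- to - from + 1
        if (n_aa < min_aa) next
        partial5 <- k == 1
        partial3 <- k == length(bounds_from)
        start_w <- frame + 3 * (from - 1)
        end_w <- frame + 3 * to + if (partial3) 0 else 3
        rows[[length(rows) + 1]] <- data.frame(
          strand = strand, frame = frame,
          start = if (strand == "+") start_w else L - end_w,
          end = if (strand == "+") end_w else L - start_w,
          aa_length = n_aa, partial5 = partial5, partial3 = partial3,
          protein = substr(prot, from, to), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_length = integer(0), partial5 = logical(0),
                      partial3 = logical(0), protein = character(0)))
  out <- do.call(rbind, rows)
  out[order(out$strand, out$frame, out$start), , drop = FALSE]
}

## --- affine-gap local alignment oracle (Smith-Waterman) ---------------
## match +1, mismatch -1, gap open 2 + 1 per base (matches the package's
## alignment scoring).  Returns score, matches, columns, and aligned
## spans on both sequences for one optimal alignment.
oracle_local_align <- function(a, b, match = 1, mismatch = -1,
                               gap_open = 2, gap_ext = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in match/mismatch
  Ix <- matrix(NEG, n + 1, m + 1)    # gap in y (consume x)
  Iy <- matrix(NEG, n + 1, m + 1)    # gap in x (consume y)
  best <- 0; bi <- 0; bj <- 0; bk <- "M"
  for (i in 1:n) for (j in 1:m) {
    sub <- if (x[i] == y[j]) match else mismatch
    M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + sub
    Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                            Ix[i, j + 1] - gap_ext)
    Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                            Iy[i + 1, j] - gap_ext)
    if (M[i + 1, j + 1] > best) {
      best <- M[i + 1, j + 1]; bi <- i; bj <- j; bk <- "M"
    }
  }
  # traceback from (bi, bj) in state M until score 0
  i <- bi; j <- bj; k <- bk
  matches <- 0L; cols <- 0L
  ei <- bi; ej <- bj
  repeat {
    if (k == "M") {
      cols <- cols + 1L
      if (x[i] == y[j]) matches <- matches + 1L
      sub <- if (x[i] == y[j]) match else mismatch
      prev <- M[i + 1, j + 1] - sub
      if (prev == 0) { i <- i - 1; j <- j - 1; break }
      k <- if (prev == M[i, j]) "M" else if (prev == Ix[i, j]) "Ix"
           else "Iy"
      i <- i - 1; j <- j - 1
    } else if (k == "Ix") {
      cols <- cols + 1L
      k <- if (Ix[i + 1, j + 1] == M[i, j + 1] - gap_open - gap_ext) "M"
           else "Ix"
      i <- i - 1
    } else {
      cols <- cols + 1L
      k <- if (Iy[i + 1, j + 1] == M[i + 1, j] - gap_open - gap_ext) "M"
           else "Iy"
      j <- j - 1
    }
  }
  list(score = best, matches = matches, columns = cols,
       a_span = c(i + 1, ei), b_span = c(j + 1, ej))
}

## --- NB exact-test enumeration oracle ---------------------------------
## NB pmf from lgamma directly (no dnbinom), full split enumeration.
oracle_nb_logpmf <- function(k, mu, phi) {
  r <- 1 / phi
  lgamma(k + r) - lgamma(r) - lfactorial(k) +
    r * log(r / (r + mu)) + k * log(mu / (r + mu))
}

oracle_nb_exact <- function(y1, y2, phi) {
  s <- y1 + y2
  if (s == 0) return(1)
  mu <- s / 2
  lp <- oracle_nb_logpmf(0:s, mu, phi) + oracle_nb_logpmf(s:0, mu, phi)
  pr <- exp(lp - max(lp))
  obs <- pr[y1 + 1]
  sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr)
}

## binomial-split analogue (Poisson limit of the NB test)
oracle_binom_exact <- function(y1, y2) {
  s <- y1 + y2
  if (s == 0) return(1)
  pr <- dbinom(0:s, s, 0.5)
  obs <- pr[y1 + 1]
  sum(pr[pr <= obs * (1 + 1e-12)]) / sum(pr)
}

## --- hypergeometric upper-tail enumeration ----------------------------
oracle_hyper_tail <- function(k, K, N, n) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## --- NB central moments by direct pmf summation -----------------------
oracle_nb_moments <- function(mu, phi, upto = 4) {
  r <- 1 / phi
  kmax <- ceiling(mu + 50 * sqrt(mu + phi * mu^2))
  k <- 0:kmax
  p <- dnbinom(k, size = r, mu = mu)
  m1 <- sum(k * p)
  cm <- vapply(2:upto, function(o) sum((k - m1)^o * p), numeric(1))
  list(mean = m1, var = cm[1], mu3 = cm[2], mu4 = cm[3])
}
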