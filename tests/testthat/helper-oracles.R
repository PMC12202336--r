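# Independent brute-force oracles.  These deliberately re-derive each
# quantity from first principles, sharing no code with the implementation.

oracle_base_counts <- function(s) {
  v <- strsplit(s, "")[[1]]
  sapply(c("A", "C", "G", "T"), function(b) sum(v == b))
}

oracle_codon_counts <- function(cds_list) {
  counts <- integer(0)
  for (cds in cds_list) {
    n <- nchar(cds)
    for (i in seq(1, n - 2, by = 3)) {
      cod <- substr(cds, i, i + 2)
      counts[cod] <- (if (is.na(counts[cod])) 0L else counts[cod]) + 1L
    }
  }
  counts
}

# --- SSR oracle: per-position maximal-run extension -----------------------
oracle_ssrs <- function(s, thresholds = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  out <- list()
  for (p in 1:6) {
    i <- 1L
    while (i + p - 1L <= n) {
      # extend the exact tandem run of the motif starting at i
      j <- i + p
      while (j <= n && v[j] == v[j - p]) j <- j + 1L
      run_nt <- j - i
      copies <- run_nt %/% p
      motif <- paste(v[i:(i + p - 1L)], collapse = "")
      primitive <- TRUE
      for (d in seq_len(p - 1L))
        if (p %% d == 0L &&
            motif == strrep(substr(motif, 1, d), p / d)) primitive <- FALSE
      left_ext <- i > 1L && v[i - 1L] == v[i - 1L + p]
      if (!left_ext && primitive && copies >= thresholds[p] &&
          !grepl("N", motif)) {
        rots <- sapply(seq_len(p), function(r)
          paste0(substr(motif, r, p), substr(motif, 1, r - 1L)))
        out[[length(out) + 1L]] <- data.frame(
          motif = sort(rots)[1], copies = copies, start = i,
          end = i + p * copies - 1L, stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  if (!length(out)) return(data.frame(motif = character(0),
                                      copies = integer(0),
                                      start = integer(0), end = integer(0)))
  unique(do.call(rbind, out))
}

# --- dispersed-repeat oracle: explicit per-diagonal window enumeration ----
oracle_dispersed <- function(s, min_len = 30L, max_len = 5000L,
                             max_mm = 3L) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  window_calls <- function(mismatch_flags, emitfun) {
    # maximal <=max_mm-mismatch windows from a logical mismatch vector
    len <- length(mismatch_flags)
    mm <- which(mismatch_flags)
    B <- c(0L, mm, len + 1L)          # 1-based boundaries with sentinels
    k <- length(mm)
    for (t in 0:max(0L, k - max_mm)) {
      lo <- B[t + 1L] + 1L
      hi <- B[min(t + max_mm + 1L, k + 1L) + 1L] - 1L
      wlen <- hi - lo + 1L
      if (wlen >= min_len && wlen <= max_len)
        emitfun(lo, hi, sum(mismatch_flags[lo:hi]))
      if (k <= max_mm) break
    }
  }
  for (d in 1:(n - 1)) {            # forward
    L <- n - d
    if (L < min_len) next
    flags <- v[1:L] != v[(1 + d):(L + d)]
    window_calls(flags, function(lo, hi, mmc) {
      rows[[length(rows) + 1L]] <<- data.frame(
        orientation = "forward", start_a = lo, end_a = hi,
        start_b = lo + d, end_b = hi + d, length = hi - lo + 1L,
        mismatches = mmc, stringsAsFactors = FALSE)
    })
  }
  rc <- rev(unname(comp[v]))
  for (d in (-(n - 1)):(n - 1)) {   # vs reverse complement
    ia <- max(1L, 1L + d); ib <- max(1L, 1L - d)
    L <- min(n - ia + 1L, n - ib + 1L)
    if (L < min_len) next
    flags <- v[ia:(ia + L - 1L)] != rc[ib:(ib + L - 1L)]
    window_calls(flags, function(lo, hi, mmc) {
      a1 <- ia + lo - 1L; a2 <- ia + hi - 1L
      b1 <- ib + lo - 1L; b2 <- ib + hi - 1L
      # map positions in the reverse complement back to forward strand
      f1 <- n - b2 + 1L; f2 <- n - b1 + 1L
      if (a1 == f1 && a2 == f2) return()  # identical interval
      st <- c(a1, f1); en <- c(a2, f2)
      o <- order(st, en)
      rows[[length(rows) + 1L]] <<- data.frame(
        orientation = "palindromic", start_a = st[o[1]], end_a = en[o[1]],
        start_b = st[o[2]], end_b = en[o[2]], length = hi - lo + 1L,
        mismatches = mmc, stringsAsFactors = FALSE)
    })
  }
  if (!length(rows))
    return(data.frame(orientation = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), length = integer(0),
                      mismatches = integer(0)))
  unique(do.call(rbind, rows))
}

# --- NG86 oracle: direct pathway enumeration per codon pair ---------------
oracle_ng86 <- function(a, b) {
  code <- mitocomp::GENETIC_CODE_4   # the code table itself is shared data
  stops <- c("TAA", "TAG")
  bases <- c("A", "C", "G", "T")
  split3 <- function(x) substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  ca <- split3(a); cb <- split3(b)
  nc <- length(ca)
  if (ca[nc] %in% stops && cb[nc] %in% stops) { ca <- ca[-nc]; cb <- cb[-nc] }
  keep <- !(ca %in% stops) & !(cb %in% stops)
  ca <- ca[keep]; cb <- cb[keep]
  syn_sites <- function(cod) {
    v <- strsplit(cod, "")[[1]]
    s <- 0
    for (pos in 1:3) for (nb in setdiff(bases, v[pos])) {
      w <- v; w[pos] <- nb
      if (code[[paste(w, collapse = "")]] == code[[cod]]) s <- s + 1
    }
    s / 3
  }
  all_perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x))
      for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    v1 <- strsplit(ca[i], "")[[1]]; v2 <- strsplit(cb[i], "")[[1]]
    dpos <- which(v1 != v2)
    if (!length(dpos)) next
    res <- NULL
    for (path in all_perms(dpos)) {
      cur <- v1; sd <- 0; nd <- 0; valid <- TRUE
      for (pos in path) {
        prev <- paste(cur, collapse = ""); cur[pos] <- v2[pos]
        nxt <- paste(cur, collapse = "")
        if (code[[nxt]] == "*" && nxt != cb[i]) { valid <- FALSE; break }
        if (code[[prev]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      }
      if (valid) res <- rbind(res, c(sd, nd))
    }
    if (is.null(res)) {
      for (path in all_perms(dpos)) {
        cur <- v1; sd <- 0; nd <- 0
        for (pos in path) {
          prev <- paste(cur, collapse = ""); cur[pos] <- v2[pos]
          nxt <- paste(cur, collapse = "")
          if (code[[prev]] == code[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        }
        res <- rbind(res, c(sd, nd))
      }
    }
    Sd <- Sd + mean(res[, 1]); Nd <- Nd + mean(res[, 2])
  }
  N <- 3 * length(ca) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ka = jc(Nd / N), Ks = jc(Sd / S))
}

# --- Needleman-Wunsch affine-gap DP oracle (score only) -------------------
oracle_nw_affine <- function(a, b, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  # gap of length L costs gap_open + L * gap_extend (Biostrings convention)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  n <- length(va); m <- length(vb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # align va[i] with vb[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (va[i] aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_extend)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sc <- if (va[i - 1] == vb[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

canon_dispersed <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(sprintf("%s:%d-%d/%d-%d", df$orientation, df$start_a, df$end_a,
               df$start_b, df$end_b))
}
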