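## Independent oracles and fixture builders shared across tests. Everything
## here is deliberately naive/brute-force and never calls the code paths it
## is used to check.

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

## Exhaustive affine-gap Smith-Waterman (score only), vectorised along
## anti-diagonals. Gap of length g costs open + g * extend.
sw_score <- function(a, b, match = 1, mismatch = -2, open = 5, extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L) # gap in a (move along b)
  F_ <- matrix(-Inf, n + 1L, m + 1L) # gap in b
  best <- 0
  for (d in 2:(n + m)) {
    i <- pmax(1L, d - m):pmin(n, d - 1L)
    j <- d - i
    sub <- ifelse(av[i] == bv[j], match, mismatch)
    e <- pmax(H[cbind(i + 1L, j)] - open - extend, E[cbind(i + 1L, j)] - extend)
    f <- pmax(H[cbind(i, j + 1L)] - open - extend, F_[cbind(i, j + 1L)] - extend)
    h <- pmax(0, H[cbind(i, j)] + sub, e, f)
    E[cbind(i + 1L, j + 1L)] <- e
    F_[cbind(i + 1L, j + 1L)] <- f
    H[cbind(i + 1L, j + 1L)] <- h
    best <- max(best, h)
  }
  best
}

## both-strand SW oracle
sw_score_2str <- function(a, b, ...) {
  max(sw_score(a, b, ...), sw_score(a, revcomp_chr(b), ...))
}

## Brute-force maximal-clique enumeration over all vertex subsets (<= 20
## vertices), via bit arithmetic on an adjacency matrix.
brute_max_cliques <- function(adj) {
  n <- nrow(adj)
  verts <- rownames(adj)
  cliques <- list()
  for (code in seq_len(2^n - 1L)) {
    S <- which(bitwAnd(code, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(S) < 2L) next
    pairs <- combn(S, 2L)
    if (!all(adj[t(pairs)] == 1L)) next
    ## maximal iff no outside vertex adjacent to all of S
    outside <- setdiff(seq_len(n), S)
    if (length(outside) && any(colSums(adj[S, outside, drop = FALSE]) == length(S))) next
    cliques[[length(cliques) + 1L]] <- sort(verts[S])
  }
  cliques[order(vapply(cliques, paste, "", collapse = "|"))]
}

## Same subset enumeration, vectorised over all 2^n subsets at once so that
## hundreds of <=15-node graphs can be checked quickly.
brute_max_cliques_fast <- function(adj) {
  n <- nrow(adj)
  verts <- rownames(adj)
  codes <- 0:(2^n - 1L)
  X <- matrix(0L, length(codes), n)
  for (b in seq_len(n)) X[, b] <- as.integer(bitwAnd(codes, bitwShiftL(1L, b - 1L)) != 0L)
  sizes <- rowSums(X)
  C <- X %*% adj                      # C[S, v] = #neighbours of v inside S
  edges_in <- rowSums(C * X) / 2
  is_clique <- sizes >= 2L & edges_in == choose(sizes, 2)
  extendable <- rowSums((C == sizes) & (X == 0L)) > 0
  keep <- which(is_clique & !extendable)
  out <- lapply(keep, function(r) sort(verts[X[r, ] == 1L]))
  out[order(vapply(out, paste, "", collapse = "|"))]
}

## Brute-force DUST mask: for every window position compute the triplet
## score by table() on substrings and mark the window if above threshold.
brute_dust_mask <- function(seq, window, threshold) {
  L <- nchar(seq)
  mask <- rep(FALSE, L)
  w <- min(window, L)
  if (L < 3L) return(mask)
  for (s in 1:(L - w + 1L)) {
    win <- substring(seq, s, s + w - 1L)
    tri <- substring(win, 1:(w - 2L), 3:w)
    tri <- tri[!grepl("N", tri)]
    cnt <- table(tri)
    score <- sum(cnt * (cnt - 1) / 2) / (w - 3L)
    if (score > threshold) mask[s:(s + w - 1L)] <- TRUE
  }
  mask
}

## Exact 3-sequence alignment by 3D dynamic programming, sum-of-pairs score
## with linear gap cost (used only on short sequences). Returns the optimal
## SP score; column cost = sum over pairs of (match/mismatch/gap).
sp3_optimal <- function(s1, s2, s3, match = 0, mismatch = 1, gap = 2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]; c_ <- strsplit(s3, "")[[1]]
  n1 <- length(a); n2 <- length(b); n3 <- length(c_)
  pc <- function(x, y) if (x == "-" && y == "-") 0 else if (x == "-" || y == "-") gap else if (x == y) match else mismatch
  D <- array(Inf, dim = c(n1 + 1L, n2 + 1L, n3 + 1L))
  D[1, 1, 1] <- 0
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    cur <- Inf
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0) next
      if (i - di < 0 || j - dj < 0 || k - dk < 0) next
      prev <- D[i - di + 1L, j - dj + 1L, k - dk + 1L]
      if (!is.finite(prev)) next
      x <- if (di) a[i] else "-"
      y <- if (dj) b[j] else "-"
      z <- if (dk) c_[k] else "-"
      cur <- min(cur, prev + pc(x, y) + pc(x, z) + pc(y, z))
    }
    D[i + 1L, j + 1L, k + 1L] <- min(D[i + 1L, j + 1L, k + 1L], cur)
  }
  D[n1 + 1L, n2 + 1L, n3 + 1L]
}

## sum-of-pairs cost of a computed multiple alignment under the same scheme
sp_cost <- function(rows, match = 0, mismatch = 1, gap = 2) {
  mat <- do.call(rbind, strsplit(rows, ""))
  total <- 0
  for (col in seq_len(ncol(mat))) {
    v <- mat[, col]
    for (p in seq_len(length(v) - 1L)) for (q in (p + 1L):length(v)) {
      x <- v[p]; y <- v[q]
      total <- total + if (x == "-" && y == "-") 0 else if (x == "-" || y == "-") gap else if (x == y) match else mismatch
    }
  }
  total
}

## small helper: rad_loci table of random loci for one species/study
make_loci <- function(n, species = "sp1", study = "s1", len = 60, prefix = "") {
  seqs <- vapply(seq_len(n), function(i) paste0(prefix, random_seq(len - nchar(prefix))), "")
  rad_loci(sprintf("%s|%s|L%03d", species, study, seq_len(n)), species, study, seqs)
}
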