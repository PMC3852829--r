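# Tiny fixture builders and independent brute-force oracles.
# The oracles deliberately share no code with the package internals.

toy_ann <- function(tss, chrom = "chr1", strand = "+") {
  GenomeAnnotation(sprintf("g%03d", seq_along(tss)),
                   rep_len(chrom, length(tss)),
                   rep_len(strand, length(tss)), tss)
}

toy_peaks <- function(start, end, summit = NA_integer_, chrom = "chr1",
                      q = 0.5, tf = "TFX", rep = "rep1") {
  PeakSet(rep_len(chrom, length(start)), start, end, summit = summit,
          q_value = q, tf_name = tf, replicate = rep)
}

# O(genes x peaks) double loop for the regulatory potential.
rp_oracle <- function(peaks, ann, D) {
  sg <- numeric(nrow(ann)); k <- integer(nrow(ann))
  for (g in seq_len(nrow(ann))) {
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != ann$chrom[g]) next
      a <- if (is.na(peaks$summit[p]))
        floor((peaks$start[p] + peaks$end[p]) / 2) else peaks$summit[p]
      d <- abs(a - ann$tss[g])
      if (d <= D) {
        sg[g] <- sg[g] + exp(-(0.5 + 4 * d / D))
        k[g] <- k[g] + 1L
      }
    }
  }
  list(S_g = sg, k = k)
}

# Exact hypergeometric upper tail by direct enumeration. For N <= ~30 all
# binomial coefficients are exact in double arithmetic.
hyper_oracle <- function(N, M, n, x) {
  hi <- min(M, n)
  if (x > hi) return(0)
  i <- max(x, 0):hi
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}

# Brute-force consensus oracle: pairwise-overlap graph, BFS components,
# then span-intersection per mixed component.
consensus_oracle <- function(a, b, min_overlap = 1L) {
  iv <- rbind(data.frame(chrom = a$chrom, start = a$start, end = a$end,
                         side = rep("a", nrow(a)), stringsAsFactors = FALSE),
              data.frame(chrom = b$chrom, start = b$start, end = b$end,
                         side = rep("b", nrow(b)), stringsAsFactors = FALSE))
  n <- nrow(iv)
  if (n == 0) return(iv[0, c("chrom", "start", "end")])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (iv$chrom[i] == iv$chrom[j] &&
        min(iv$end[i], iv$end[j]) - max(iv$start[i], iv$start[j]) >= min_overlap)
      adj[i, j] <- TRUE
  }
  comp <- rep(NA_integer_, n); cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  out <- NULL
  for (k in unique(comp)) {
    m <- iv[comp == k, , drop = FALSE]
    if (!all(c("a", "b") %in% m$side)) next
    sa <- m[m$side == "a", ]; sb <- m[m$side == "b", ]
    s <- max(min(sa$start), min(sb$start))
    e <- min(max(sa$end), max(sb$end))
    out <- rbind(out, data.frame(chrom = m$chrom[1], start = s, end = e,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out)) return(iv[0, c("chrom", "start", "end")])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Count of merged (>=1 bp overlap collapsed) intervals, via IRanges.
merged_count <- function(ps) {
  if (nrow(ps) == 0) return(0L)
  sum(vapply(split(seq_len(nrow(ps)), ps$chrom), function(i)
    length(IRanges::reduce(IRanges::IRanges(ps$start[i] + 1L, ps$end[i]))),
    1L))
}

random_peakset <- function(n, span = 1000L, max_w = 120L, tf = "TFR") {
  s <- sample.int(span, n, replace = TRUE)
  toy_peaks(s, s + sample.int(max_w, n, replace = TRUE), tf = tf)
}
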