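# Independent straight-line oracles. These deliberately re-derive every
# quantity from first principles (loops, no shared code paths with the
# package internals) so that agreement is evidence, not tautology.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# --- conservation track oracle ------------------------------------------

oracle_henikoff <- function(m) {
  n <- nrow(m)
  raw <- rep(0, n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    keep <- which(!(col %in% c("-", "X")))
    if (!length(keep)) next
    r <- length(unique(col[keep]))
    for (i in keep) {
      s <- sum(col[keep] == col[i])
      raw[i] <- raw[i] + 1 / (r * s)
    }
  }
  raw / sum(raw)
}

oracle_column_p <- function(col, w, pseudocount) {
  w <- w / sum(w)
  p <- rep(0, 20)
  names(p) <- AA20
  for (i in seq_along(col))
    if (col[i] %in% AA20) p[col[i]] <- p[col[i]] + w[i]
  gap_fraction <- sum(w[col == "-"])
  p <- p + pseudocount
  if (sum(p) == 0) p[] <- 1 / 20 else p <- p / sum(p)
  list(p = p, gap_fraction = gap_fraction)
}

oracle_jsd <- function(p, q, lambda = 0.5) {
  r <- lambda * p + (1 - lambda) * q
  term <- function(a) {
    s <- 0
    for (i in seq_along(a)) if (a[i] > 0) s <- s + a[i] * log2(a[i] / r[i])
    s
  }
  lambda * term(p) + (1 - lambda) * term(q)
}

oracle_track <- function(m, lambda = 0.5, window = 3, window_weight = 0.5,
                         pseudocount = 1e-7, gap_penalty = TRUE,
                         use_weights = TRUE,
                         background = blosum62_background()) {
  n <- nrow(m)
  w <- if (use_weights) oracle_henikoff(m) else rep(1 / n, n)
  L <- ncol(m)
  raw <- numeric(L)
  gapf <- numeric(L)
  for (j in seq_len(L)) {
    cp <- oracle_column_p(m[, j], w, pseudocount)
    d <- oracle_jsd(cp$p, background, lambda)
    d <- min(max(d, 0), 1)
    if (gap_penalty) d <- d * (1 - cp$gap_fraction)
    raw[j] <- d
    gapf[j] <- cp$gap_fraction
  }
  windowed <- raw
  for (j in seq_len(L)) {
    nb <- setdiff(seq(max(1, j - window), min(L, j + window)), j)
    if (length(nb) && window > 0 && window_weight > 0)
      windowed[j] <- (1 - window_weight) * raw[j] +
        window_weight * mean(raw[nb])
  }
  list(raw = raw, windowed = windowed, gap_fraction = gapf)
}

random_alignment_matrix <- function(n, L, gap_rate = 0.1) {
  m <- matrix(sample(AA20, n * L, replace = TRUE), n, L)
  gaps <- matrix(runif(n * L) < gap_rate, n, L)
  # keep at least one residue per row and per column
  for (i in seq_len(n)) if (all(gaps[i, ])) gaps[i, 1] <- FALSE
  for (j in seq_len(L)) if (all(gaps[, j])) gaps[1, j] <- FALSE
  m[gaps] <- "-"
  m
}

# --- contact oracle ------------------------------------------------------

oracle_residue_pairs <- function(structure, cutoff = 5.0) {
  at <- structure$atoms
  out <- character(0)
  n <- nrow(at)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (at$chain[i] == at$chain[j]) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d <= cutoff) {
        a <- paste(at$chain[i], at$resno[i])
        b <- paste(at$chain[j], at$resno[j])
        out <- c(out, if (a < b) paste(a, "|", b) else paste(b, "|", a))
      }
    }
  }
  sort(unique(out))
}

contact_pair_keys <- function(contacts) {
  if (!nrow(contacts)) return(character(0))
  a <- paste(contacts$chain_a, contacts$resno_a)
  b <- paste(contacts$chain_b, contacts$resno_b)
  sort(unique(ifelse(a < b, paste(a, "|", b), paste(b, "|", a))))
}

# --- motif scan oracle ---------------------------------------------------

oracle_scan <- function(sequence, region, motifs = default_motifs()) {
  chars <- strsplit(sequence, "")[[1]]
  res <- list()
  for (k in seq_len(nrow(motifs))) {
    pat <- strsplit(motifs$pattern[k], "")[[1]]
    len <- length(pat)
    for (start in region[1]:(region[2] - len + 1)) {
      if (start < 1 || start + len - 1 > length(chars)) next
      ok <- TRUE
      for (p in seq_len(len)) {
        if (pat[p] != "x" && chars[start + p - 1] != pat[p]) {
          ok <- FALSE
          break
        }
      }
      if (ok)
        res[[length(res) + 1]] <- data.frame(
          motif = motifs$name[k], start = start,
          match = paste(chars[start:(start + len - 1)], collapse = ""))
    }
  }
  if (!length(res))
    return(data.frame(motif = character(), start = integer(),
                      match = character()))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$motif), ]
  rownames(out) <- NULL
  out
}

# --- UPGMA oracle --------------------------------------------------------

# Average-linkage merge heights by brute force: inter-cluster distance is
# always the mean over all cross pairs of the ORIGINAL distance matrix.
oracle_upgma_heights <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    bestd <- Inf
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < bestd) {
          bestd <- d
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, bestd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# --- misc ----------------------------------------------------------------

# Build a minimal conservation-track-shaped data frame for report tests.
fake_track <- function(jsd) {
  data.frame(column = seq_along(jsd), raw_jsd = jsd, windowed_jsd = jsd,
             gap_fraction = rep(0, length(jsd)))
}

identity_mapping <- function(n) data.frame(ref_pos = seq_len(n),
                                           column = seq_len(n))
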