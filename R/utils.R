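# Internal helpers shared across modules.

# Label connected foreground components with 8-connectivity.
# EBImage::bwlabel() uses 4-connectivity, so labels that touch only
# diagonally are merged afterwards with a union-find over label pairs.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  nlab <- max(lab)
  if (nlab <= 1L) {
    storage.mode(lab) <- "integer"
    return(lab)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (i, j) with (i+1, j+1) and (i+1, j-1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  parent <- seq_len(nlab)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

# Sliding quantile over a numeric vector with partial windows at the edges.
sliding_quantile <- function(x, width, prob) {
  zoo::rollapply(x, width = width, FUN = quantile, probs = prob,
                 names = FALSE, partial = TRUE, align = "center")
}

# Significance stars at the conventional 0.05/0.01/0.001/0.0001 thresholds.
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  sd(x) / sqrt(length(x))
}

assert_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1))) {
    abort("`mask` must be a matrix with values in {0, 1}.")
  }
  invisible(mask)
}
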