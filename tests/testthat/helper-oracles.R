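# independent brute-force MRMR (MID) oracle used to check the greedy trace
bruteMrmr <- function(X, labels, nBins = 10L) {
  disc <- function(x) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = nBins + 1)))
    if (length(br) < 2) return(rep(1L, length(x)))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  mi <- function(a, b) {
    tab <- table(a, b) / length(a)
    pa <- rowSums(tab); pb <- colSums(tab)
    nz <- tab > 0
    sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  }
  ids <- colnames(X)
  D <- lapply(ids, function(id) disc(X[, id])); names(D) <- ids
  y <- as.integer(factor(labels))
  sel <- character(0); rest <- ids
  while (length(rest)) {
    score <- sapply(rest, function(f) {
      r <- mi(D[[f]], y)
      if (!length(sel)) r
      else r - mean(sapply(sel, function(s) mi(D[[f]], D[[s]])))
    })
    best <- rest[which.max(score)]
    sel <- c(sel, best); rest <- setdiff(rest, best)
  }
  sel
}
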