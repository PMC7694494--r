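# Independent oracles: every brute-force recount here is written against
# the definition, not the package's implementation path.

aln_from <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
  alignment_matrix(seqs)
}

random_alignment <- function(n_rows, n_cols, gap_prob = 0.1, n_prob = 0.05) {
  pool <- c("A", "C", "G", "T", "-", "N")
  prob <- c(rep((1 - gap_prob - n_prob) / 4, 4), gap_prob, n_prob)
  seqs <- vapply(seq_len(n_rows), function(i)
    paste(sample(pool, n_cols, replace = TRUE, prob = prob), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", seq_len(n_rows))
  alignment_matrix(seqs)
}

# Pi by direct definition: all unordered pairs, all columns
brute_pi <- function(aln, start = 0, end = aln_length(aln)) {
  mat <- aln$mat[, (start + 1):end, drop = FALSE]
  n <- nrow(mat)
  ds <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m <- 0; x <- 0
    for (k in seq_len(ncol(mat))) {
      a <- mat[i, k]; b <- mat[j, k]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        m <- m + 1
        if (a != b) x <- x + 1
      }
    }
    if (m > 0) ds <- c(ds, x / m)
  }
  if (!length(ds)) NA_real_ else mean(ds)
}

# PIC by direct per-column recount
brute_pics <- function(aln) {
  mat <- aln$mat
  cnt <- 0L
  for (k in seq_len(ncol(mat))) {
    tab <- table(mat[, k][mat[, k] %in% c("A", "C", "G", "T")])
    if (sum(tab >= 2) >= 2) cnt <- cnt + 1L
  }
  cnt
}

# longest exact inverted-repeat pair by full quadratic scan (linear, i.e.
# for sequences whose repeat does not wrap the origin)
brute_ir <- function(seq, min_len) {
  sv <- strsplit(seq, "")[[1]]
  n <- length(sv)
  rcv <- rev(chartr("ACGTN", "TGCAN", sv))
  eq <- outer(sv, rcv, "==")
  best <- NULL
  # diagonals of eq: runs of TRUE are common substrings of seq and revcomp
  for (d in (-(n - 1)):(n - 1)) {
    i0 <- max(1, 1 + d); j0 <- max(1, 1 - d)
    len <- n - abs(d)
    v <- eq[cbind(i0:(i0 + len - 1), j0:(j0 + len - 1))]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_len)) {
      l <- r$lengths[k]
      i <- i0 + ends[k] - l           # 1-based start in seq
      j <- j0 + ends[k] - l           # 1-based start in revcomp
      a <- c(i - 1, i - 1 + l)        # 0-based half-open in seq
      b <- c(n - j - l + 1, n - j + 1)
      lo <- pmin(a[1], b[1]); hi <- pmax(a[1], b[1])
      if (min(a[2], b[2]) <= max(a[1], b[1])) {  # disjoint copies only
        cand <- list(len = l, start = lo, other = hi)
        if (is.null(best) || l > best$len ||
            (l == best$len && lo < best$start)) best <- cand
      }
    }
  }
  best
}

# independent amino-acid lookup (seqinr) for the NG86 oracles
oracle_translate <- function(codon) {
  toupper(seqinr::translate(tolower(strsplit(codon, "")[[1]])))
}

# exhaustive pathway enumeration for one codon pair, built on seqinr
oracle_pair_diffs <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  pos <- which(va != vb)
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  perms <- if (length(pos) == 1) list(pos) else {
    prm <- function(x) if (length(x) <= 1) list(x) else
      do.call(c, lapply(seq_along(x), function(i)
        lapply(prm(x[-i]), function(r) c(x[i], r))))
    prm(pos)
  }
  tally <- function(skip_stop) {
    tot <- c(syn = 0, nonsyn = 0); used <- 0
    for (ord in perms) {
      cur <- va; steps <- c(syn = 0, nonsyn = 0); ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- vb[p]
        aa1 <- oracle_translate(paste(cur, collapse = ""))
        aa2 <- oracle_translate(paste(nxt, collapse = ""))
        if (aa2 == "*" && skip_stop) { ok <- FALSE; break }
        if (aa1 == aa2 && aa1 != "*") steps["syn"] <- steps["syn"] + 1
        else steps["nonsyn"] <- steps["nonsyn"] + 1
        cur <- nxt
      }
      if (ok) { tot <- tot + steps; used <- used + 1 }
    }
    list(tot = tot, used = used)
  }
  res <- tally(TRUE)
  if (res$used == 0) res <- tally(FALSE)
  res$tot / res$used
}

# random clean (sense, non-stop) codon
random_codon <- function() {
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE), collapse = "")
    if (oracle_translate(cd) != "*") return(cd)
  }
}

# closed-form simple OLS
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2); sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r = sxy / sqrt(sxx * sum((y - mean(y))^2)))
}

fast_config <- function(seed, ...) {
  simulation_config(seed = seed, genome_plan = toy_genome_plan(), ...)
}

# single long neutral-ish gene plan for rate-recovery experiments
long_gene_plan <- function(n_genes = 5, codons = 1500) {
  len <- codons * 3
  genes <- data.frame(
    name = sprintf("orf%03d", seq_len(n_genes)),
    kind = "PCG", region = "LSC", len = len, n_exons = 1, strand = "+",
    stringsAsFactors = FALSE)
  list(lsc = as.integer(n_genes * (len + 200) + 200), ssc = 800L,
       ir = 600L, genes = genes)
}
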