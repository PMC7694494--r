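# Quadripartite structure: detect the pair of exact inverted repeats on the
# circular sequence, derive LSC/SSC as the two gaps between the copies, and
# summarize genomes in the conventional comparison-table schema.
#
# The IR definition is exact (no mismatches) with maximal bidirectional
# extension; ties between equally long candidates are broken by the smallest
# start coordinate, so detection is deterministic and oracle-checkable.

#' Detect the inverted-repeat pair of a circular genome
#'
#' Finds the maximal-length pair of disjoint intervals whose sequences are
#' exact reverse complements of each other, searching on the circular
#' sequence (seed-and-extend over non-overlapping seed tiles, which is
#' guaranteed to find any repeat of at least `min_len`). The two gaps
#' between the copies become the single-copy regions, the larger labeled LSC.
#' Genome order is taken as LSC, IRb, SSC, IRa.
#'
#' @param genome an `annotated_genome` (or a plain sequence string)
#' @param min_len minimum repeat length to report; default 10 kb, the
#'   conventional floor for plastome IRs
#' @return a `quadripartite` object with 0-based half-open intervals
#'   (`$ira`, `$irb`, `$lsc`, `$ssc`, possibly wrapping past the origin, in
#'   which case end > genome length and coordinates are mod length),
#'   junction positions `$junctions` (JLB, JSB, JSA, JLA: 0-based position of
#'   the first base of the downstream region) and `$found`. When no repeat
#'   reaches `min_len` a structured no-IR result (`found = FALSE`) is
#'   returned, not an error.
#' @export
find_inverted_repeats <- function(genome, min_len = 10000) {
  seq <- if (inherits(genome, "annotated_genome")) genome$seq else toupper(genome)
  if (min_len < 1) stop2("min_len must be >= 1")
  n <- nchar(seq)
  no_ir <- structure(list(found = FALSE, genome_length = n), class = "quadripartite")
  if (n < 2 * min_len) return(no_ir)

  sv <- seq_to_chars(seq)
  cv <- comp_chars(sv)
  s2 <- paste0(seq, seq)                 # doubled for circular matching
  k <- max(20L, min(as.integer((min_len + 1) %/% 2), 5000L))

  cand <- list()
  seen <- character(0)
  seed_starts <- seq(0L, n - 1L, by = k)  # 0-based tile starts
  for (a in seed_starts) {
    seed <- substring(s2, a + 1L, a + k)
    pat <- revcomp(seed)
    hits <- Biostrings::matchPattern(pat, Biostrings::BString(s2))
    qs <- BiocGenerics::start(hits) - 1L  # 0-based in doubled seq
    qs <- unique(cpos(qs, n))
    for (q in qs) {
      # seed occupies [a, a+k); its reverse complement occupies [q, q+k).
      # Pairing: position i in copy1 pairs with C - i in copy2.
      C <- a + (q + k - 1L)
      ext <- extend_ir_pair(sv, cv, n, lo = a, hi = a + k - 1L, C = C)
      if (is.null(ext)) next
      key <- paste(ext$len, cpos(min(ext$lo, C - ext$hi), n), sep = ":")
      if (key %in% seen) next
      seen <- c(seen, key)
      cand[[length(cand) + 1L]] <- ext
    }
  }
  if (!length(cand)) return(no_ir)
  lens <- vapply(cand, `[[`, 0L, "len")
  best_len <- max(lens)
  if (best_len < min_len) return(no_ir)
  best <- cand[lens == best_len]
  # two intervals of the winning pair, as (start mod n, len)
  ivs <- lapply(best, function(e) {
    s1 <- cpos(e$lo, n); s2i <- cpos(e$C - e$hi, n)
    m <- sort(c(s1, s2i))
    list(a = m[1], b = m[2], len = e$len)
  })
  starts <- vapply(ivs, `[[`, 0, "a")
  pick <- ivs[[which.min(starts)]]
  build_quadripartite(pick$a, pick$b, pick$len, n)
}

# maximal bidirectional extension of a paired anchor; block-vectorized.
# Positions are unreduced (can be negative / >= n); pairing i <-> C - i.
extend_ir_pair <- function(sv, cv, n, lo, hi, C) {
  max_total <- n %/% 2L                  # copies must stay disjoint
  ok_at <- function(i) sv[cpos(i, n) + 1L] == cv[cpos(C - i, n) + 1L]
  if (!all(ok_at(lo:hi))) return(NULL)   # anchor must pair (guards dup hits)
  B <- 2048L
  repeat {                               # extend right
    if (hi - lo + 1L >= max_total) break
    idx <- (hi + 1L):min(hi + B, lo + max_total - 1L)
    good <- ok_at(idx)
    w <- which(!good)
    if (length(w)) { hi <- idx[1L] + w[1L] - 2L; break }
    hi <- idx[length(idx)]
    if (length(idx) < B) break
  }
  repeat {                               # extend left
    if (hi - lo + 1L >= max_total) break
    idx <- (lo - 1L):max(lo - B, hi - max_total + 1L)
    good <- ok_at(idx)
    w <- which(!good)
    if (length(w)) { lo <- idx[1L] - w[1L] + 2L; break }
    lo <- idx[length(idx)]
    if (length(idx) < B) break
  }
  len <- hi - lo + 1L
  s1 <- cpos(lo, n); s2 <- cpos(C - hi, n)
  # reject overlapping copies (palindrome self-match)
  d <- cpos(s2 - s1, n)
  if (d < len || (n - d) < len) return(NULL)
  list(lo = lo, hi = hi, C = C, len = len)
}

build_quadripartite <- function(a, b, len, n) {
  # copies at [a, a+len) and [b, b+len) on the circle, a < b
  gap1 <- cpos(b - (a + len), n)         # gap after copy A, before copy B
  gap2 <- cpos(a - (b + len), n)         # gap after copy B, before copy A
  if (gap1 >= gap2) {
    lsc <- c(a + len, a + len + gap1); ssc <- c(b + len, b + len + gap2)
    irb <- c(b, b + len); ira <- c(a, a + len)
  } else {
    lsc <- c(b + len, b + len + gap2); ssc <- c(a + len, a + len + gap1)
    irb <- c(a, a + len); ira <- c(b, b + len)
  }
  junctions <- c(JLB = cpos(irb[1], n), JSB = cpos(ssc[1], n),
                 JSA = cpos(ira[1], n), JLA = cpos(lsc[1], n))
  structure(list(found = TRUE, genome_length = n,
                 ira = ira, irb = irb, lsc = lsc, ssc = ssc,
                 ir_len = len, lsc_len = max(gap1, gap2),
                 ssc_len = min(gap1, gap2), junctions = junctions),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$found) {
    cat("quadripartite: no inverted repeat found (genome ",
        x$genome_length, " bp)\n", sep = "")
  } else {
    cat("quadripartite: LSC ", x$lsc_len, " / IR ", x$ir_len,
        " x2 / SSC ", x$ssc_len, " bp (genome ", x$genome_length, ")\n",
        sep = "")
  }
  invisible(x)
}

region_interval_positions <- function(iv, n) cpos(iv[1]:(iv[2] - 1L), n)

#' Compare single-copy/IR junctions across genomes
#'
#' For each genome and each junction (JLB, JSB, JSA, JLA) reports the
#' junction position, the nearest gene on each side, and the overlap length
#' when a gene spans the junction (the length of the shorter of the two gene
#' segments the junction cuts).
#'
#' @param structures list of `list(genome = annotated_genome, structure =
#'   quadripartite)` pairs
#' @return data frame with one row per genome x junction; positions 1-based
#' @export
junction_table <- function(structures) {
  if (!length(structures)) stop2("at least one structure is required")
  rows <- list()
  for (gs in structures) {
    g <- gs$genome; q <- gs$structure
    if (!isTRUE(q$found)) next
    n <- q$genome_length
    spans <- if (length(g$features))
      t(vapply(g$features, feature_span, c(0, 0))) else matrix(0, 0, 2)
    nms <- vapply(g$features, `[[`, "", "name")
    for (jn in names(q$junctions)) {
      j <- q$junctions[[jn]]
      left <- right <- span_gene <- NA_character_
      overlap <- NA_integer_
      if (nrow(spans)) {
        # circular distances from junction boundary j
        dl <- cpos(j - spans[, 2], n)    # gene ends upstream of j
        dr <- cpos(spans[, 1] - j, n)    # gene starts downstream of j
        inside <- cpos(j - spans[, 1], n) < (spans[, 2] - spans[, 1])
        left <- nms[which.min(ifelse(inside, 0L, dl))]
        right <- nms[which.min(ifelse(inside, 0L, dr))]
        if (any(inside)) {
          i <- which(inside)[1]
          span_gene <- nms[i]
          overlap <- min(cpos(j - spans[i, 1], n),
                         cpos(spans[i, 2] - j, n))
        } else overlap <- 0L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g$id, junction = jn, position = j + 1L,
        gene_left = left, gene_right = right,
        spanning_gene = span_gene, overlap_bp = overlap,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Summarize a genome in the standard plastome comparison schema
#'
#' Region lengths, GC content per region (percent, rounded half-up to one
#' decimal), gene counts (total and unique normalized names), per-kind
#' counts and coding lengths, intron statistics. A gene counts as "in IR"
#' when at least half of its exonic span lies inside either IR copy.
#'
#' @param genome an `annotated_genome`
#' @param structure a `quadripartite` from [find_inverted_repeats()]
#' @return one-row data frame (`genome_summary`)
#' @export
summarize_genome <- function(genome, structure) {
  sv <- seq_to_chars(genome$seq)
  n <- length(sv)
  gc_pct <- function(pos) {
    v <- sv[pos + 1L]
    round_half_up(100 * gc_fraction(v), 1)
  }
  if (isTRUE(structure$found)) {
    ir_pos <- c(region_interval_positions(structure$ira, n),
                region_interval_positions(structure$irb, n))
    lsc_pos <- region_interval_positions(structure$lsc, n)
    ssc_pos <- region_interval_positions(structure$ssc, n)
    gc_lsc <- gc_pct(lsc_pos); gc_ssc <- gc_pct(ssc_pos)
    gc_ir <- gc_pct(region_interval_positions(structure$ira, n))
    lsc_len <- structure$lsc_len; ssc_len <- structure$ssc_len
    ir_len <- structure$ir_len
    in_ir_mask <- logical(n); in_ir_mask[ir_pos + 1L] <- TRUE
  } else {
    gc_lsc <- gc_ssc <- gc_ir <- NA_real_
    lsc_len <- ssc_len <- ir_len <- NA_integer_
    in_ir_mask <- logical(n)
  }

  feats <- genome$features
  kinds <- vapply(feats, `[[`, "", "kind")
  nms <- vapply(feats, `[[`, "", "name")
  lens <- vapply(feats, feature_len, 0)
  in_ir <- vapply(feats, function(f) {
    pos <- unlist(apply(f$exons, 1, function(e) e[1]:(e[2] - 1L),
                        simplify = FALSE))
    mean(in_ir_mask[pos + 1L]) >= 0.5
  }, logical(1))
  if (!length(feats)) in_ir <- logical(0)

  nex <- vapply(feats, function(f) nrow(f$exons), 0L)
  # per unique gene name: kind, whether any copy is duplicated in the IR,
  # and the exon count (comparison tables report the per-kind columns at the
  # unique-gene level, while coding lengths count every copy)
  uniq <- unique(nms)
  ukind <- vapply(uniq, function(u) kinds[nms == u][1], "")
  udup <- vapply(uniq, function(u) sum(nms == u) >= 2, logical(1))
  uin_ir <- vapply(uniq, function(u) any(in_ir[nms == u]), logical(1))
  unex <- vapply(uniq, function(u) max(nex[nms == u]), 0L)

  data.frame(
    genome = genome$id,
    genome_size = n,
    lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
    gc_total = round_half_up(100 * gc_fraction(sv), 1),
    gc_lsc = gc_lsc, gc_ssc = gc_ssc, gc_ir = gc_ir,
    total_genes = length(feats), unique_genes = length(uniq),
    dup_in_ir = sum(udup & uin_ir),
    pcg_total = sum(ukind == "PCG"), pcg_in_ir = sum(uin_ir & ukind == "PCG"),
    trna_total = sum(ukind == "tRNA"), trna_in_ir = sum(uin_ir & ukind == "tRNA"),
    rrna_total = sum(ukind == "rRNA"), rrna_in_ir = sum(uin_ir & ukind == "rRNA"),
    coding_len = sum(lens),
    pcg_len = sum(lens[kinds == "PCG"]),
    trna_len = sum(lens[kinds == "tRNA"]),
    rrna_len = sum(lens[kinds == "rRNA"]),
    intron_genes = sum(unex >= 2),
    three_exon_genes = sum(unex >= 3),
    stringsAsFactors = FALSE)
}
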