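# Region classification (exon / intron / intergenic spacer) in alignment
# coordinates, per-region divergence, parsimony-informative character
# counts, per-gene codon alignments and the gap-filtered supermatrix.

#' Classify alignment columns into exon / intron / IGS regions
#'
#' Derives genome-coordinate regions from a genome's features (introns are
#' the gaps between consecutive exons of one gene; intergenic spacers the
#' gaps between consecutive features, named `geneA-geneB` by their flanks;
#' exons take precedence where annotations overlap), then lifts them to
#' alignment coordinates through the gap structure of the genome's row:
#' every column maps to the last reference base at or before it. Columns
#' ahead of the first reference base stay unassigned. Zero-length spacers
#' are omitted.
#'
#' @param genome an `annotated_genome`
#' @param aln an `alignment_matrix` containing the genome as one row
#' @param row row name (or index) of the genome in `aln`
#' @return data frame (`name`, `kind` in exon/intron/IGS, `start`, `end`
#'   0-based half-open alignment intervals, non-overlapping)
#' @export
classify_regions <- function(genome, aln, row) {
  rowv <- aln$mat[row, ]
  ungapped <- chars_to_seq(rowv[rowv != "-"])
  if (!identical(ungapped, genome$seq))
    stop2("ungapped alignment row '", row, "' does not match genome ",
          genome$id)
  n <- nchar(genome$seq)
  lab <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)

  feats <- genome$features
  if (length(feats)) {
    spans <- t(vapply(feats, feature_span, c(0, 0)))
    ord <- order(spans[, 1], spans[, 2])
    # introns first, exons after, so exons win inside a gene's footprint
    for (f in feats[ord]) {
      sp <- feature_span(f)
      idx <- (sp[1] + 1L):sp[2]
      fill <- is.na(lab[idx])
      lab[idx][fill] <- f$name; kind[idx][fill] <- "intron"
    }
    for (f in feats[ord]) {
      for (r in seq_len(nrow(f$exons))) {
        idx <- (f$exons[r, 1] + 1L):f$exons[r, 2]
        lab[idx] <- f$name; kind[idx] <- "exon"
      }
    }
    # spacers between consecutive feature spans (circular wrap included)
    spans <- spans[ord, , drop = FALSE]
    nm <- vapply(feats[ord], `[[`, "", "name")
    merged_end <- cummax(spans[, 2])
    for (k in seq_len(nrow(spans))) {
      a_end <- merged_end[k]
      nxt <- if (k < nrow(spans)) spans[k + 1, 1] else n + spans[1, 1]
      if (nxt <= a_end) next
      b_name <- if (k < nrow(spans)) nm[k + 1] else nm[1]
      igs <- paste0(strip_anticodon(nm[k]), "-", strip_anticodon(b_name))
      idx <- (cpos(a_end:(nxt - 1L), n)) + 1L
      fill <- is.na(lab[idx])
      lab[idx][fill] <- igs; kind[idx][fill] <- "IGS"
    }
  }

  # lift per-base labels through the row's gap structure: column -> index of
  # last reference base at or before it (0 for columns before the first)
  ref_idx <- cumsum(aln$mat[row, ] != "-")
  col_lab <- ifelse(ref_idx > 0, lab[pmax(ref_idx, 1)], NA_character_)
  col_kind <- ifelse(ref_idx > 0, kind[pmax(ref_idx, 1)], NA_character_)
  key <- paste(col_lab, col_kind, sep = "\r")
  key[is.na(col_lab)] <- NA_character_
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !is.na(r$values)
  parts <- strsplit(r$values[keep], "\r", fixed = TRUE)
  data.frame(name = vapply(parts, `[[`, "", 1),
             kind = vapply(parts, `[[`, "", 2),
             start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

strip_anticodon <- function(x) sub("^(trn[A-Za-z]+)-[A-Z]{3}$", "\\1", x)

#' Per-region nucleotide diversity
#'
#' Pi over each named region's full column span (pieces of a split region
#' are pooled), using the same pairwise-deletion rule as the window scan.
#' @param aln an `alignment_matrix`
#' @param map region map from [classify_regions()]
#' @return data frame (`name`, `kind`, `length`, `pi`, `n_pairs_used`)
#'   sorted by Pi descending
#' @export
region_pi <- function(aln, map) {
  keys <- unique(map[, c("name", "kind")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- map$name == keys$name[i] & map$kind == keys$kind[i]
    cols <- unlist(lapply(which(sel), function(j)
      (map$start[j] + 1L):map$end[j]))
    p <- pi_over_columns(aln, cols)
    data.frame(name = keys$name[i], kind = keys$kind[i],
               length = length(cols), pi = p$pi,
               n_pairs_used = p$n_pairs_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-ifelse(is.na(out$pi), -Inf, out$pi)), , drop = FALSE]
}

pi_over_columns <- function(aln, cols) {
  sub <- aln$mat[, cols, drop = FALSE]
  prs <- pair_index(nrow(sub))
  d <- numeric(0); used <- 0L
  for (k in seq_len(ncol(prs))) {
    a <- sub[prs[1, k], ]; b <- sub[prs[2, k], ]
    comp <- a %in% BASES & b %in% BASES
    if (!any(comp)) next
    used <- used + 1L
    d <- c(d, sum(a[comp] != b[comp]) / sum(comp))
  }
  list(pi = if (used == 0) NA_real_ else mean(d), n_pairs_used = used)
}

#' Count parsimony-informative characters
#'
#' A column is parsimony-informative when, counting only states in
#' {A,C,G,T} (gaps and N are missing data), at least two distinct states
#' each occur in at least two rows.
#'
#' @param aln an `alignment_matrix`
#' @return integer count of informative columns
#' @export
count_pics <- function(aln) {
  if (aln_nseq(aln) < 4) {
    warning("fewer than 4 sequences: no column can be parsimony-informative")
    return(0L)
  }
  counts <- vapply(BASES, function(b) colSums(aln$mat == b),
                   numeric(aln_length(aln)))
  if (aln_length(aln) == 1) counts <- matrix(counts, nrow = 1)
  sum(rowSums(counts >= 2) >= 2)
}

#' PIC table for a set of gene alignments
#'
#' @param set a `gene_alignment_set` from [extract_codon_alignments()]
#' @return data frame (`gene`, `pics`, `length`, `percent` with the percent
#'   rendered to 2 decimals), sorted by PIC count descending
#' @export
pic_table <- function(set) {
  rows <- lapply(names(set$alignments), function(g) {
    a <- set$alignments[[g]]
    p <- count_pics(a)
    data.frame(gene = g, pics = p, length = aln_length(a),
               percent = round_half_up(100 * p / aln_length(a), 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$pics), , drop = FALSE]
}

# ---- codon alignments -------------------------------------------------------

#' Identity protein "aligner" for equal-length sequences
#'
#' The pluggable aligner contract: a function from a named character vector
#' of protein sequences to a named character vector of aligned proteins of
#' equal length (gaps as `-`). This default refuses length differences
#' rather than guessing.
#' @param prots named character vector of protein sequences
#' @return named character vector of aligned proteins
#' @export
aligner_identity <- function(prots) {
  if (length(unique(nchar(prots))) != 1)
    stop2("aligner_identity needs equal-length proteins; supply a real ",
          "aligner (e.g. aligner_mafft) for length-variable genes")
  prots
}

#' MAFFT-based protein aligner
#'
#' Shells out to a `mafft` executable (L-INS-i). Only used when explicitly
#' requested; no test depends on it.
#' @param prots named character vector of protein sequences
#' @param exe mafft executable
#' @return named character vector of aligned proteins
#' @export
aligner_mafft <- function(prots, exe = "mafft") {
  if (Sys.which(exe) == "") stop2("mafft executable not found")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(prots), "\n", prots), fin)
  status <- system2(exe, c("--localpair", "--maxiterate", "1000", "--anysymbol",
                           fin), stdout = fout, stderr = FALSE)
  if (status != 0) stop2("mafft failed with status ", status)
  ss <- Biostrings::readBStringSet(fout)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out[names(prots)]
}

translate_cds <- function(cds) {
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve")))
}

#' Extract per-gene codon alignments across genomes
#'
#' For each protein-coding gene annotated in every genome: the CDS is
#' extracted exon-joined and strand-oriented (for genes duplicated in the
#' inverted repeat the first copy by genome coordinate is used; copies are
#' identical by construction of the IR), translated, aligned at the protein
#' level through the pluggable `aligner`, and the codons threaded back
#' through the gapped proteins (back-translation). Genes whose length is
#' not divisible by 3 are excluded with a logged reason; internal stop
#' codons are flagged but kept.
#'
#' @param genomes list of `annotated_genome` objects
#' @param aligner protein aligner function (see [aligner_identity()])
#' @param genes optional character vector restricting the gene set
#' @return a `gene_alignment_set`: list with `alignments` (named list of
#'   codon `alignment_matrix`), `flagged` (data frame of exclusions and
#'   warnings) and `taxa`
#' @export
extract_codon_alignments <- function(genomes, aligner = aligner_identity,
                                     genes = NULL) {
  ids <- vapply(genomes, `[[`, "", "id")
  per_genome <- lapply(genomes, function(g) {
    f <- g$features
    keep <- vapply(f, function(x) x$kind == "PCG" && x$copy == 1L, logical(1))
    f <- f[keep]
    stats::setNames(f, vapply(f, `[[`, "", "name"))
  })
  common <- Reduce(intersect, lapply(per_genome, names))
  if (!is.null(genes)) common <- intersect(common, genes)
  missing <- setdiff(unique(unlist(lapply(per_genome, names))), common)
  if (length(missing))
    message(length(missing), " gene(s) absent from at least one genome: ",
            paste(utils::head(sort(missing), 8), collapse = ", "),
            if (length(missing) > 8) ", ..." else "")
  flagged <- data.frame(gene = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  alignments <- list()
  for (g in sort(common)) {
    cds <- vapply(seq_along(genomes), function(i)
      extract_cds(genomes[[i]], per_genome[[i]][[g]]), character(1))
    names(cds) <- ids
    if (any(nchar(cds) %% 3 != 0)) {
      flagged <- rbind(flagged, data.frame(
        gene = g, reason = "length not divisible by 3", stringsAsFactors = FALSE))
      message("excluding ", g, ": CDS length not divisible by 3")
      next
    }
    prots <- vapply(cds, translate_cds, character(1))
    aligned <- aligner(prots)
    rows <- vapply(seq_along(cds), function(i)
      thread_codons(cds[[i]], aligned[[ids[i]]]), character(1))
    names(rows) <- ids
    if (any(grepl("\\*", substr(prots, 1, nchar(prots) - 1))))
      flagged <- rbind(flagged, data.frame(
        gene = g, reason = "internal stop codon", stringsAsFactors = FALSE))
    alignments[[g]] <- alignment_matrix(rows)
  }
  structure(list(alignments = alignments, flagged = flagged, taxa = ids),
            class = "gene_alignment_set")
}

thread_codons <- function(cds, aligned_prot) {
  chars <- seq_to_chars(aligned_prot)
  out <- character(length(chars))
  pos <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") out[i] <- "---"
    else { out[i] <- substring(cds, pos * 3L + 1L, pos * 3L + 3L); pos <- pos + 1L }
  }
  paste(out, collapse = "")
}

#' @export
print.gene_alignment_set <- function(x, ...) {
  cat("gene_alignment_set: ", length(x$alignments), " genes x ",
      length(x$taxa), " taxa\n", sep = "")
  invisible(x)
}

# ---- supermatrix ------------------------------------------------------------

#' Build a gap-filtered supermatrix with partitions
#'
#' Concatenates the codon alignments in alphabetical gene order, removes
#' columns whose gap fraction exceeds `max_gap_fraction` (strictly greater:
#' a column at exactly the threshold is retained), and returns the filtered
#' matrix together with a partition table mapping each gene and codon
#' position to its retained columns (RAxML-style range expressions, 1-based).
#'
#' @param set a `gene_alignment_set`
#' @param max_gap_fraction removal threshold on the per-column gap fraction
#'   (default 0.2)
#' @return list with `aln` (the filtered `alignment_matrix`), `partitions`
#'   (data frame `partition`, `sites`), `n_removed`, `n_retained`,
#'   `total_input_columns`
#' @export
build_supermatrix <- function(set, max_gap_fraction = 0.2) {
  if (!length(set$alignments)) stop2("empty gene alignment set")
  genes <- sort(names(set$alignments))
  taxa <- set$taxa
  mats <- lapply(set$alignments[genes], function(a) a$mat[taxa, , drop = FALSE])
  big <- do.call(cbind, mats)
  gap_frac <- colMeans(big == "-")
  keep <- gap_frac <= max_gap_fraction
  newcol <- cumsum(keep)

  lens <- vapply(mats, ncol, 0L)
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  names(offsets) <- genes
  parts <- list()
  for (gi in seq_along(genes)) {
    for (cp in 1:3) {
      orig <- seq(offsets[gi] + cp, offsets[gi] + lens[gi], by = 3L)
      ret <- newcol[orig][keep[orig]]
      parts[[length(parts) + 1L]] <- data.frame(
        partition = sprintf("%s_codon%d", genes[gi], cp),
        sites = compress_ranges(ret), n_sites = length(ret),
        stringsAsFactors = FALSE)
    }
  }
  rows <- apply(big[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- taxa
  list(aln = alignment_matrix(rows),
       partitions = do.call(rbind, parts),
       n_removed = sum(!keep), n_retained = sum(keep),
       total_input_columns = length(keep))
}

# RAxML-style site expression: arithmetic runs with step 3 become "i-j\3",
# consecutive runs "i-j", singletons "i"
compress_ranges <- function(idx) {
  if (!length(idx)) return("")
  out <- character(0)
  i <- 1L
  while (i <= length(idx)) {
    for (stp in c(3L, 1L)) {
      j <- i
      while (j < length(idx) && idx[j + 1L] - idx[j] == stp) j <- j + 1L
      if (j > i || stp == 1L) break
    }
    if (j == i) out <- c(out, as.character(idx[i]))
    else if (stp == 3L) out <- c(out, sprintf("%d-%d\\3", idx[i], idx[j]))
    else out <- c(out, sprintf("%d-%d", idx[i], idx[j]))
    i <- j + 1L
  }
  paste(out, collapse = ",")
}

#' Write a RAxML-style partition file
#' @param sm result of [build_supermatrix()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_partitions <- function(sm, path) {
  keep <- sm$partitions$n_sites > 0
  writeLines(sprintf("DNA, %s = %s", sm$partitions$partition[keep],
                     sm$partitions$sites[keep]), path)
  invisible(path)
}

#' Write an alignment in relaxed sequential PHYLIP format
#' @param aln an `alignment_matrix`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_phylip <- function(aln, path) {
  rows <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(c(sprintf("%d %d", aln_nseq(aln), aln_length(aln)),
               sprintf("%s  %s", aln$names, rows)), path)
  invisible(path)
}
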