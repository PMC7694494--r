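# Plastome simulator with a replayable ground-truth registry. An ancestor
# genome with the quadripartite architecture (LSC | IRb | SSC | IRa, IRb the
# exact reverse complement of IRa) and planted canonical ORFs is evolved
# into n taxa by per-site substitutions whose expected pairwise divergence
# is theta scaled by region-specific multipliers, omega-controlled
# accept/reject on coding changes, and intron/spacer-only indels. The true
# multiple alignment is induced by the indel registry, so statistic tests
# never depend on a heuristic aligner.

#' Simulation configuration
#'
#' @param seed integer seed; the whole simulation is deterministic under it
#' @param genome_plan region lengths and gene plan, see
#'   [default_genome_plan()] / [toy_genome_plan()]
#' @param n_taxa number of taxa (default 5, a small congeneric sample)
#' @param theta expected genome-wide pairwise divergence per site (default
#'   0.01: low interspecific divergence, windows mostly below 0.03)
#' @param region_rate_multipliers relative substitution rates for exon,
#'   intron and IGS sites (defaults 0.3 / 1 / 3, normalized internally so
#'   the genome-wide expectation stays theta)
#' @param n_hotspot_igs number of spacers given an extra rate boost to act
#'   as planted divergence hotspots
#' @param hotspot_multiplier extra rate factor for those spacers
#' @param indel_rate indel events per eligible (intron/IGS) site per taxon
#' @param indel_mean_len mean of the geometric indel length distribution
#' @param large_indel_lens lengths of one-off large spacer insertions
#'   (default 431 and 258 bp, the length polymorphism scale seen in real
#'   congeneric plastomes)
#' @param omega_true dN/dS the coding accept/reject step targets; scalar or
#'   named per-gene vector
#' @param gc_by_region background GC fraction used when drawing LSC, SSC
#'   and IR sequence
#' @return a `simulation_config`
#' @export
simulation_config <- function(seed = 1L,
                              genome_plan = default_genome_plan(),
                              n_taxa = 5L,
                              theta = 0.01,
                              region_rate_multipliers =
                                c(exon = 0.3, intron = 1, IGS = 3),
                              n_hotspot_igs = 6L,
                              hotspot_multiplier = 2.5,
                              indel_rate = 2e-4,
                              indel_mean_len = 40,
                              large_indel_lens = c(431L, 258L),
                              omega_true = 0.2,
                              gc_by_region =
                                c(LSC = 0.35, SSC = 0.31, IR = 0.42)) {
  stopifnot(theta >= 0, all(region_rate_multipliers > 0), indel_rate >= 0,
            all(omega_true >= 0), n_taxa >= 2)
  structure(list(seed = as.integer(seed), genome_plan = genome_plan,
                 n_taxa = as.integer(n_taxa), theta = theta,
                 region_rate_multipliers = region_rate_multipliers,
                 n_hotspot_igs = as.integer(n_hotspot_igs),
                 hotspot_multiplier = hotspot_multiplier,
                 indel_rate = indel_rate, indel_mean_len = indel_mean_len,
                 large_indel_lens = as.integer(large_indel_lens),
                 omega_true = omega_true, gc_by_region = gc_by_region),
            class = "simulation_config")
}

#' Full-scale plastome gene plan
#'
#' Region lengths and a gene plan emulating a typical Lamiaceae plastome:
#' about 83.5 kb LSC, 17.5 kb SSC and 25.7 kb IRs; 114 unique genes (80
#' protein-coding, 30 tRNA, 4 rRNA) of which 18 are duplicated in the IR;
#' 18 intron-containing genes, two of them with three exons. The table
#' ships in `extdata/plastome_gene_plan.tsv` and is user-editable.
#' @return a genome plan list (`lsc`, `ssc`, `ir`, `genes`)
#' @export
default_genome_plan <- function() {
  path <- system.file("extdata", "plastome_gene_plan.tsv", package = "plastdiv")
  genes <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  list(lsc = 83500L, ssc = 17500L, ir = 25700L, genes = genes)
}

#' Small plastome plan for fast experiments
#'
#' Same architecture at reduced scale; gene names are real plastid symbols
#' so downstream naming conventions apply unchanged.
#' @param lsc,ssc,ir region lengths in bp
#' @return a genome plan list
#' @export
toy_genome_plan <- function(lsc = 12000L, ssc = 2800L, ir = 2700L) {
  genes <- data.frame(
    name = c("psbA", "matK", "rpoB", "rbcL", "petA", "rpl16", "clpP",
             "trnH-GUG", "trnK-UUU",
             "ndhF", "ycf1",
             "rrn16", "rpl2", "trnV-GAC"),
    kind = c(rep("PCG", 7), "tRNA", "tRNA", "PCG", "PCG", "rRNA", "PCG", "tRNA"),
    region = c(rep("LSC", 9), "SSC", "SSC", "IR", "IR", "IR"),
    len = c(1062, 1530, 1809, 1428, 963, 411, 591, 74, 72, 933, 1050,
            900, 822, 72),
    n_exons = c(1, 1, 1, 1, 1, 2, 3, 1, 2, 1, 1, 1, 2, 1),
    strand = c("-", "-", "-", "+", "+", "-", "+", "-", "-", "-", "+",
               "+", "-", "+"),
    stringsAsFactors = FALSE)
  list(lsc = as.integer(lsc), ssc = as.integer(ssc), ir = as.integer(ir),
       genes = genes)
}

rand_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

STOPS <- c("TAA", "TAG", "TGA")

rand_orf <- function(len, gc) {
  # canonical ORF: ATG + non-stop codons + stop; len divisible by 3
  stopifnot(len %% 3 == 0, len >= 9)
  ncod <- as.integer(len / 3 - 2)
  draw <- function(k) {
    m <- matrix(rand_bases(3L * k, gc), ncol = 3)
    paste0(m[, 1], m[, 2], m[, 3])
  }
  cods <- draw(ncod)
  repeat {
    bad <- which(cods %in% STOPS)
    if (!length(bad)) break
    cods[bad] <- draw(length(bad))
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}

# place one region's genes: returns list(seq chars, features local 0-based).
# Coding sequence is drawn GC-richer than spacers/introns, as in real
# plastomes, so composition and divergence are linked through the region
# structure (conserved genes are the GC-rich stretches).
build_region <- function(genes, region_len, gc, min_gap = 30L) {
  gc_gene <- min(gc + 0.05, 0.8)
  gc_spacer <- max(gc - 0.06, 0.15)
  ng <- nrow(genes)
  intron_lens <- lapply(seq_len(ng), function(i) {
    k <- genes$n_exons[i] - 1L
    if (k <= 0) integer(0) else as.integer(round(stats::runif(k, 250, 600)))
  })
  footprints <- genes$len + vapply(intron_lens, sum, 0L)
  spare <- region_len - sum(footprints) - (ng + 1L) * min_gap
  if (spare < 0) stop2("gene plan exceeds region capacity (need ",
                       sum(footprints) + (ng + 1L) * min_gap, " bp, have ",
                       region_len, ")")
  w <- stats::runif(ng + 1L)
  extra <- floor(spare * w / sum(w))
  extra[ng + 1L] <- spare - sum(extra[seq_len(ng)])
  gaps <- min_gap + extra

  parts <- list()
  feats <- list()
  cursor <- 0L
  for (i in seq_len(ng)) {
    parts[[length(parts) + 1L]] <- rand_bases(gaps[i], gc_spacer)
    cursor <- cursor + gaps[i]
    gene_seq <- if (genes$kind[i] == "PCG") rand_orf(genes$len[i], gc_gene)
                else chars_to_seq(rand_bases(genes$len[i], gc_gene))
    nex <- genes$n_exons[i]
    # split the transcript into exons at random interior points
    if (nex > 1) {
      cuts <- sort(sample(seq_len(genes$len[i] - 1L), nex - 1L))
      bounds <- c(0L, cuts, genes$len[i])
    } else bounds <- c(0L, genes$len[i])
    exon_seqs <- substring(gene_seq, bounds[-length(bounds)] + 1L,
                           bounds[-1])
    ilens <- intron_lens[[i]]
    # genomic layout on the plus strand: for minus-strand genes the
    # transcript runs right-to-left, so exon order is reversed and pieces
    # reverse-complemented
    if (genes$strand[i] == "+") {
      pieces <- exon_seqs
    } else {
      pieces <- rev(vapply(exon_seqs, revcomp, character(1)))
    }
    local <- list(); pos <- cursor
    for (j in seq_along(pieces)) {
      parts[[length(parts) + 1L]] <- seq_to_chars(pieces[j])
      local[[j]] <- c(pos, pos + nchar(pieces[j]))
      pos <- pos + nchar(pieces[j])
      if (j < length(pieces)) {
        il <- ilens[j]
        parts[[length(parts) + 1L]] <- rand_bases(il, gc_spacer)
        pos <- pos + il
      }
    }
    cursor <- pos
    ex <- do.call(rbind, local)
    if (genes$strand[i] == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    feats[[i]] <- gene_feature(genes$name[i], genes$kind[i], genes$strand[i], ex)
  }
  parts[[length(parts) + 1L]] <- rand_bases(gaps[ng + 1L], gc_spacer)
  chars <- unlist(parts)
  stopifnot(length(chars) == region_len)
  list(chars = chars, feats = feats)
}

shift_feature <- function(f, offset) {
  f$exons <- f$exons + as.integer(offset)
  f
}

mirror_feature <- function(f, ir_len, offset) {
  # mirror an IRa-local feature into IRb: local [s,e) -> [L-e, L-s), strand
  # flipped; keeping row order preserves 5'->3' coding order
  ex <- cbind(ir_len - f$exons[, 2], ir_len - f$exons[, 1]) + as.integer(offset)
  gene_feature(f$name, f$kind, if (f$strand == "+") "-" else "+", ex)
}

#' Simulate an ancestral plastome
#'
#' Builds the ancestor from the gene plan: random background sequence at
#' region-specific GC, planted canonical ORFs for protein-coding genes, IRb
#' an exact reverse complement of IRa. Deterministic under the config seed.
#'
#' @param config a [simulation_config()]
#' @return list with `genome` (an `annotated_genome`), `structure` (the true
#'   `quadripartite`), and `region_map` (true genome-coordinate regions)
#' @export
simulate_ancestor <- function(config) {
  set.seed(config$seed)
  plan <- config$genome_plan
  gc <- config$gc_by_region
  g_lsc <- build_region(plan$genes[plan$genes$region == "LSC", ], plan$lsc,
                        gc[["LSC"]])
  g_ssc <- build_region(plan$genes[plan$genes$region == "SSC", ], plan$ssc,
                        gc[["SSC"]])
  g_ira <- build_region(plan$genes[plan$genes$region == "IR", ], plan$ir,
                        gc[["IR"]])
  L <- plan$lsc; I <- plan$ir; S <- plan$ssc
  ira_seq <- chars_to_seq(g_ira$chars)
  irb_chars <- seq_to_chars(revcomp(ira_seq))
  # genome order: LSC [0,L) | IRb [L,L+I) | SSC [L+I,L+I+S) | IRa [.. +I)
  chars <- c(g_lsc$chars, irb_chars, g_ssc$chars, g_ira$chars)
  # make the planted IR exactly maximal: break the chance complementarity
  # that would let the repeat extend past its planted junctions. The pairing
  # beyond the copies is (last LSC base <-> first LSC base) and (first SSC
  # base <-> last SSC base); all four sit in spacer sequence.
  if (chars[L] == comp_chars(chars[1]))
    chars[1] <- sample(setdiff(BASES, chars[1]), 1)
  if (chars[L + I + 1L] == comp_chars(chars[L + I + S]))
    chars[L + I + S] <- sample(setdiff(BASES, chars[L + I + S]), 1)
  feats <- c(lapply(g_lsc$feats, shift_feature, 0L),
             lapply(g_ira$feats, mirror_feature, ir_len = I, offset = L),
             lapply(g_ssc$feats, shift_feature, L + I),
             lapply(g_ira$feats, shift_feature, L + I + S))
  feats <- assign_copy_indices(feats)
  genome <- annotated_genome("ancestor", chars_to_seq(chars), feats,
                             source = "simulated")
  n <- L + 2L * I + S
  structure_truth <- build_quadripartite(a = L, b = L + I + S, len = I, n = n)
  region_map <- genome_region_map(genome)
  list(genome = genome, structure = structure_truth, region_map = region_map)
}

# true region map in genome coordinates (same labeling rules as
# classify_regions, without the alignment lift)
genome_region_map <- function(genome) {
  lab <- genome_region_labels(genome)
  key <- paste(lab$name, lab$kind, sep = "\r")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- !startsWith(r$values, "NA\r")
  parts <- strsplit(r$values[keep], "\r", fixed = TRUE)
  data.frame(name = vapply(parts, `[[`, "", 1),
             kind = vapply(parts, `[[`, "", 2),
             start = starts[keep], end = ends[keep], stringsAsFactors = FALSE)
}

genome_region_labels <- function(genome) {
  n <- nchar(genome$seq)
  lab <- rep(NA_character_, n)
  kind <- rep(NA_character_, n)
  feats <- genome$features
  if (length(feats)) {
    spans <- t(vapply(feats, feature_span, c(0, 0)))
    ord <- order(spans[, 1], spans[, 2])
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
  list(name = lab, kind = kind)
}

#' Evolve taxa from a simulated ancestor
#'
#' Substitutions are Bernoulli per site and taxon with probabilities chosen
#' so that the expected pairwise divergence equals theta times the
#' normalized region multiplier (the inversion accounts for coincident
#' hits, and coding sites are compensated for the omega accept/reject step
#' so expectations hold there too). Nonsynonymous proposals are accepted
#' with probability omega; proposals creating stop codons are rejected.
#' Indels fall only in introns and spacers, with geometric lengths plus the
#' configured one-off large spacer insertions.
#'
#' @param ancestor result of [simulate_ancestor()]
#' @param config the same [simulation_config()]
#' @return list with `genomes` (list of `annotated_genome`), `truth`
#'   (a `simulation_truth`: substituted pre-indel sequences, indel registry,
#'   planted hotspots, per-gene accepted substitution counts, per-site
#'   mutation counts)
#' @export
evolve_taxa <- function(ancestor, config) {
  set.seed(config$seed + 1L)
  genome <- ancestor$genome
  n <- nchar(genome$seq)
  anc <- seq_to_chars(genome$seq)
  lab <- genome_region_labels(genome)
  kind <- lab$kind
  kind[is.na(kind)] <- "IGS"            # unannotated leftovers behave as IGS

  mult <- config$region_rate_multipliers[kind]
  hotspots <- data.frame(name = character(0), start = integer(0),
                         end = integer(0), stringsAsFactors = FALSE)
  igs_tab <- ancestor$region_map[ancestor$region_map$kind == "IGS", ]
  igs_tab <- igs_tab[order(-(igs_tab$end - igs_tab$start)), ]
  # hotspot spacers: single-copy spacers long enough to dominate a window
  sc <- igs_tab[igs_tab$end - igs_tab$start >= 300, ]
  st0 <- ancestor$structure
  if (isTRUE(st0$found)) {
    in_ir <- function(s, e) (s < st0$irb[2] && e > st0$irb[1]) ||
      (s < st0$ira[2] && e > st0$ira[1])
    sc <- sc[!mapply(in_ir, sc$start, sc$end), , drop = FALSE]
  }
  nh <- min(config$n_hotspot_igs, nrow(sc))
  if (nh > 0) {
    pick <- sc[sample(seq_len(nrow(sc)), nh), ]
    for (i in seq_len(nh)) {
      idx <- (pick$start[i] + 1L):pick$end[i]
      mult[idx] <- mult[idx] * config$hotspot_multiplier
    }
    hotspots <- pick[, c("name", "start", "end")]
  }
  mult <- mult / mean(mult)
  d_site <- pmin(config$theta * mult, 0.70)
  p_site <- 0.75 * (1 - sqrt(1 - 4 * d_site / 3))

  # coding acceptance compensation (protein-coding exons only). Only the
  # first copy of IR-duplicated genes is evolved under coding control; the
  # second copy is regenerated by IR homogenization below.
  pcg <- genome$features[vapply(genome$features, function(f)
    f$kind == "PCG" && !f$non_canonical && f$copy == 1L, logical(1))]
  omega_of <- function(g) {
    ot <- config$omega_true
    if (is.null(names(ot))) return(unname(ot[1]))
    v <- unname(ot[g])
    if (is.na(v)) mean(ot) else v
  }
  code <- the_codon_tables()$code
  cds_maps <- lapply(pcg, function(f) cds_position_map(f))
  q_site <- p_site
  is_coding <- logical(n)
  for (fi in seq_along(pcg)) {
    f <- pcg[[fi]]; mp <- cds_maps[[fi]]
    omega <- omega_of(f$name)
    cds <- anc[mp$gpos + 1L]
    cds[mp$strand_flip] <- comp_chars(cds[mp$strand_flip])
    acc <- codon_site_acceptance(cds, omega, code)
    # compensate the accept/reject thinning by the gene-wide mean acceptance
    # so the gene's average divergence stays theta * exon multiplier while
    # per-site acceptance still enforces omega
    q_site[mp$gpos + 1L] <- pmin(1, p_site[mp$gpos + 1L] / max(mean(acc), 1e-9))
    is_coding[mp$gpos + 1L] <- TRUE
  }

  taxa_names <- sprintf("tax%02d", seq_len(config$n_taxa))
  subs_mat <- matrix(rep(anc, config$n_taxa), nrow = config$n_taxa,
                     byrow = TRUE, dimnames = list(taxa_names, NULL))
  site_mut_counts <- integer(n)
  gene_events <- list()

  for (t in seq_len(config$n_taxa)) {
    hits <- which(stats::runif(n) < q_site)
    nc_hits <- hits[!is_coding[hits]]
    if (length(nc_hits)) {
      alt <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                   G = c("A", "C", "T"), T = c("A", "C", "G"))
      subs_mat[t, nc_hits] <- alt[cbind(match(subs_mat[t, nc_hits], BASES),
                                        sample.int(3L, length(nc_hits),
                                                   replace = TRUE))]
      site_mut_counts[nc_hits] <- site_mut_counts[nc_hits] + 1L
    }
    hit_set <- hits[is_coding[hits]]
    for (fi in seq_along(pcg)) {
      f <- pcg[[fi]]; mp <- cds_maps[[fi]]
      omega <- omega_of(f$name)
      local <- match(hit_set, mp$gpos + 1L)
      sel <- which(!is.na(local))
      if (!length(sel)) next
      cds <- subs_mat[t, mp$gpos + 1L]
      cds[mp$strand_flip] <- comp_chars(cds[mp$strand_flip])
      nsyn <- nnon <- 0L
      tb_cnt <- the_codon_tables()
      for (ci in sort(local[sel])) {
        cod_i <- (ci - 1L) %/% 3L
        off <- (ci - 1L) %% 3L
        codon <- cds[(cod_i * 3L + 1L):(cod_i * 3L + 3L)]
        cod_str <- chars_to_seq(codon)
        aa1 <- code[[cod_str]]
        # event thinning and target choice are set up so the realized
        # nonsynonymous rate per counting-method nonsynonymous site (which
        # includes stop targets) is omega times the synonymous rate: stop
        # targets carry zero weight and their share is redistributed onto
        # the viable nonsynonymous targets
        ns <- tb_cnt$syn_cnt[cod_str, off + 1L]
        nn <- tb_cnt$nonstop_nonsyn_cnt[cod_str, off + 1L]
        nstp <- 3L - ns - nn
        # when every nonsynonymous target is a stop the share cannot be
        # realized and is dropped, not folded into synonymous events
        tot <- ns + if (nn > 0L) omega * (nn + nstp) else 0
        if (stats::runif(1) >= min(1, tot / 3)) next
        alts <- setdiff(BASES, codon[off + 1L])
        ws <- vapply(alts, function(b) {
          newc <- codon; newc[off + 1L] <- b
          aa2 <- code[[chars_to_seq(newc)]]
          if (aa2 == "*") 0
          else if (aa2 == aa1) 1
          else if (nn > 0L) omega * (nn + nstp) / nn else 0
        }, numeric(1))
        if (sum(ws) == 0) next
        prop <- sample(alts, 1, prob = ws)
        newc <- codon; newc[off + 1L] <- prop
        aa2 <- code[[chars_to_seq(newc)]]
        cds[ci] <- prop
        if (aa1 == aa2) nsyn <- nsyn + 1L else nnon <- nnon + 1L
        gp <- mp$gpos[ci] + 1L
        site_mut_counts[gp] <- site_mut_counts[gp] + 1L
      }
      back <- cds
      back[mp$strand_flip] <- comp_chars(back[mp$strand_flip])
      subs_mat[t, mp$gpos + 1L] <- back
      gene_events[[length(gene_events) + 1L]] <- data.frame(
        taxon = taxa_names[t], gene = f$name, copy = f$copy,
        syn = nsyn, nonsyn = nnon, stringsAsFactors = FALSE)
    }
    # IR homogenization: the two repeat copies evolve as one locus (as in
    # real plastomes, where gene conversion keeps them identical), so the
    # IRa copy is regenerated as the reverse complement of IRb
    st <- ancestor$structure
    if (isTRUE(st$found)) {
      irb_idx <- (st$irb[1] + 1L):st$irb[2]
      ira_idx <- st$ira[2]:(st$ira[1] + 1L)
      subs_mat[t, ira_idx] <- comp_chars(subs_mat[t, irb_idx])
    }
  }

  registry <- draw_indels(genome, kind, config, taxa_names,
                          exclude = ancestor$structure)

  truth <- structure(list(
    ancestor = ancestor, subs = subs_mat, registry = registry,
    hotspots = hotspots,
    gene_events = if (length(gene_events)) do.call(rbind, gene_events)
                  else data.frame(),
    site_mut_counts = site_mut_counts, taxa = taxa_names,
    config = config), class = "simulation_truth")

  aln <- truth_alignment(truth)
  genomes <- lapply(seq_along(taxa_names), function(t) {
    seq_t <- aln_ungap(aln, taxa_names[t])
    feats <- remap_features(genome$features, registry, taxa_names[t], n)
    annotated_genome(taxa_names[t], seq_t, feats, source = "simulated")
  })
  list(genomes = genomes, truth = truth)
}

# per-CDS-position genome coordinates and strand flags
cds_position_map <- function(f) {
  gpos <- integer(0); flip <- logical(0)
  for (r in seq_len(nrow(f$exons))) {
    if (f$strand == "+") {
      gpos <- c(gpos, f$exons[r, 1]:(f$exons[r, 2] - 1L))
      flip <- c(flip, rep(FALSE, f$exons[r, 2] - f$exons[r, 1]))
    } else {
      gpos <- c(gpos, (f$exons[r, 2] - 1L):f$exons[r, 1])
      flip <- c(flip, rep(TRUE, f$exons[r, 2] - f$exons[r, 1]))
    }
  }
  list(gpos = gpos, strand_flip = flip)
}

# per-site event-thinning probability: synonymous targets at full rate,
# the combined nonsynonymous-plus-stop target share at omega times it
# (matching the weighted target choice in the coding hit loop)
codon_site_acceptance <- function(cds, omega, code) {
  tb <- the_codon_tables()
  nc <- length(cds) %/% 3L
  m <- matrix(cds[seq_len(3L * nc)], ncol = 3, byrow = TRUE)
  codons <- paste0(m[, 1], m[, 2], m[, 3])
  syn <- tb$syn_cnt[codons, , drop = FALSE]
  nns <- tb$nonstop_nonsyn_cnt[codons, , drop = FALSE]
  acc <- pmin(1, (syn + omega * (3 - syn) * (nns > 0)) / 3)
  as.vector(t(acc))
}

draw_indels <- function(genome, kind, config, taxa_names, exclude = NULL) {
  n <- nchar(genome$seq)
  eligible <- which(kind %in% c("intron", "IGS"))
  if (!is.null(exclude) && isTRUE(exclude$found)) {
    # keep indels out of the homogenized repeats: single-copy regions only
    in_ir <- c((exclude$ira[1] + 1L):exclude$ira[2],
               (exclude$irb[1] + 1L):exclude$irb[2])
    eligible <- setdiff(eligible, in_ir)
  }
  reg <- list()
  if (length(eligible) && config$indel_rate > 0) {
    runs <- split(eligible, cumsum(c(1L, diff(eligible) != 1L)))
    run_of <- integer(n)
    for (ri in seq_along(runs)) run_of[runs[[ri]]] <- ri
    for (t in seq_along(taxa_names)) {
      k <- stats::rpois(1, config$indel_rate * length(eligible))
      if (k == 0) next
      pos <- sample(eligible, min(k, length(eligible)))
      lens <- stats::rgeom(length(pos), 1 / config$indel_mean_len) + 1L
      type <- sample(c("ins", "del"), length(pos), replace = TRUE)
      for (i in seq_along(pos)) {
        run <- runs[[run_of[pos[i]]]]
        if (type[i] == "del") {
          l <- min(lens[i], run[length(run)] - pos[i] + 1L)
          reg[[length(reg) + 1L]] <- data.frame(
            taxon = taxa_names[t], type = "del", anchor = pos[i] - 1L,
            length = l, seq = "", stringsAsFactors = FALSE)
        } else {
          reg[[length(reg) + 1L]] <- data.frame(
            taxon = taxa_names[t], type = "ins", anchor = pos[i] - 1L,
            length = lens[i],
            seq = chars_to_seq(rand_bases(lens[i], 0.32)),
            stringsAsFactors = FALSE)
        }
      }
    }
    # planted large spacer insertions: longest single-copy spacers, one
    # random taxon each
    igs_runs <- runs[order(-vapply(runs, length, 0L))]
    for (j in seq_along(config$large_indel_lens)) {
      if (j > length(igs_runs)) break
      run <- igs_runs[[j]]
      at <- run[ceiling(length(run) / 2)]
      l <- config$large_indel_lens[j]
      reg[[length(reg) + 1L]] <- data.frame(
        taxon = sample(taxa_names, 1), type = "ins", anchor = at - 1L,
        length = l, seq = chars_to_seq(rand_bases(l, 0.30)),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(reg)) {
    return(data.frame(taxon = character(0), type = character(0),
                      anchor = integer(0), length = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  registry <- do.call(rbind, reg)
  sanitize_registry(registry, n)
}

# resolve within-taxon conflicts: merge overlapping deletions, drop
# insertions anchored inside a deleted span of the same taxon
sanitize_registry <- function(registry, n) {
  out <- list()
  for (t in unique(registry$taxon)) {
    sub <- registry[registry$taxon == t, , drop = FALSE]
    dels <- sub[sub$type == "del", , drop = FALSE]
    if (nrow(dels)) {
      dels <- dels[order(dels$anchor), , drop = FALSE]
      merged <- list()
      cs <- dels$anchor[1]; ce <- dels$anchor[1] + dels$length[1]
      for (i in seq_len(nrow(dels))[-1]) {
        if (dels$anchor[i] <= ce) ce <- max(ce, dels$anchor[i] + dels$length[i])
        else { merged[[length(merged) + 1L]] <- c(cs, ce)
               cs <- dels$anchor[i]; ce <- dels$anchor[i] + dels$length[i] }
      }
      merged[[length(merged) + 1L]] <- c(cs, ce)
      dels <- do.call(rbind, lapply(merged, function(m) data.frame(
        taxon = t, type = "del", anchor = m[1], length = m[2] - m[1],
        seq = "", stringsAsFactors = FALSE)))
    }
    ins <- sub[sub$type == "ins", , drop = FALSE]
    if (nrow(ins) && nrow(dels)) {
      bad <- vapply(ins$anchor, function(a)
        any(a > dels$anchor & a < dels$anchor + dels$length), logical(1))
      ins <- ins[!bad, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- rbind(dels, ins)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$anchor, res$taxon), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Replay the indel registry into the exact multiple alignment
#'
#' Deletions become gap runs in the owning taxon's row; each insertion
#' becomes a column block carried by its taxon only (independent insertions
#' at the same anchor are stacked, not aligned to each other). Ungapping
#' any row reproduces that taxon's simulated sequence exactly.
#'
#' @param truth a `simulation_truth` from [evolve_taxa()]
#' @return an `alignment_matrix`
#' @export
truth_alignment <- function(truth) {
  subs <- truth$subs
  reg <- truth$registry
  n <- ncol(subs)
  nt <- nrow(subs)
  if (nrow(reg)) {
    if (any(reg$anchor < 0 | reg$anchor > n) ||
        any(reg$type == "del" & reg$anchor + reg$length > n))
      stop2("corrupt indel registry")
  }
  base <- subs
  ins <- reg[reg$type == "ins", , drop = FALSE]
  dels <- reg[reg$type == "del", , drop = FALSE]
  for (i in seq_len(nrow(dels)))
    base[dels$taxon[i], (dels$anchor[i] + 1L):(dels$anchor[i] + dels$length[i])] <- "-"

  if (!nrow(ins)) {
    rows <- apply(base, 1, paste, collapse = "")
    names(rows) <- rownames(subs)
    return(alignment_matrix(rows))
  }
  ins <- ins[order(ins$anchor, ins$taxon), , drop = FALSE]
  L <- n + sum(ins$length)
  mat <- matrix("-", nrow = nt, ncol = L, dimnames = list(rownames(subs), NULL))
  # cumadd[i] = columns inserted at anchors <= i-1 (anchors are 0..n: an
  # insertion at anchor a sits between ancestor bases a and a+1, 1-based)
  add <- as.integer(tapply(ins$length, factor(ins$anchor, levels = 0:n), sum))
  add[is.na(add)] <- 0L
  cumadd <- cumsum(add)
  anc_col <- seq_len(n) + cumadd[seq_len(n)]
  mat[, anc_col] <- base
  pre <- c(0L, cumadd)                     # pre[a+1] = inserted at anchors < a
  used_at <- integer(n + 1L)
  for (i in seq_len(nrow(ins))) {
    a <- ins$anchor[i]
    start <- a + pre[a + 1L] + used_at[a + 1L] + 1L
    mat[ins$taxon[i], start:(start + ins$length[i] - 1L)] <-
      seq_to_chars(ins$seq[i])
    used_at[a + 1L] <- used_at[a + 1L] + ins$length[i]
  }
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- rownames(subs)
  alignment_matrix(rows)
}

# remap ancestor-coordinate features into a taxon's own coordinates
remap_features <- function(features, registry, taxon, n) {
  sub <- registry[registry$taxon == taxon, , drop = FALSE]
  dels <- sub[sub$type == "del", , drop = FALSE]
  ins <- sub[sub$type == "ins", , drop = FALSE]
  mappos <- function(pos) {
    # pos: 0-based ancestor coordinate of a retained base
    del_before <- if (nrow(dels))
      sum(pmin(pmax(pos - dels$anchor, 0L), dels$length)) else 0L
    ins_before <- if (nrow(ins)) sum(ins$length[ins$anchor <= pos]) else 0L
    pos - del_before + ins_before
  }
  lapply(features, function(f) {
    ex <- f$exons
    for (r in seq_len(nrow(ex))) {
      ex[r, 1] <- mappos(ex[r, 1])
      ex[r, 2] <- mappos(ex[r, 2] - 1L) + 1L
    }
    f$exons <- matrix(as.integer(ex), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
    f
  })
}

#' Run a complete simulation
#'
#' Convenience wrapper: ancestor, taxa, truth and truth alignment in one
#' call.
#' @param config a [simulation_config()]
#' @return list with `ancestor`, `genomes`, `truth`, `alignment`
#' @export
simulate_plastomes <- function(config = simulation_config()) {
  anc <- simulate_ancestor(config)
  ev <- evolve_taxa(anc, config)
  list(ancestor = anc, genomes = ev$genomes, truth = ev$truth,
       alignment = truth_alignment(ev$truth))
}
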