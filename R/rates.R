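# Synonymous / nonsynonymous substitution rates by the Nei-Gojobori (1986)
# counting method: potential sites from enumeration of all nine single-base
# changes per codon, observed differences apportioned by averaging over all
# minimal mutational pathways (pathways through stop codons excluded), and
# the Jukes-Cantor correction d = -(3/4) ln(1 - 4p/3).

the_codon_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  # Biostrings uses T-containing codon names already
  stats::setNames(as.character(gc), names(gc))
}

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

codon_aa <- function(codon) the_codon_tables()$aa[[codon]]

the_codon_tables <- function() {
  if (!is.null(the_codon_cache$tables)) return(the_codon_cache$tables)
  code <- genetic_code()
  codons <- all_codons()
  aa <- as.list(code[codons])
  syn_sites <- stats::setNames(numeric(length(codons)), codons)
  # per codon and position: counts of the 3 single-base changes that are
  # synonymous / nonsynonymous-but-not-stop (used by the simulator's
  # acceptance compensation as well as the site counting here)
  syn_cnt <- nonstop_nonsyn_cnt <-
    matrix(0L, length(codons), 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    v <- seq_to_chars(cd)
    for (p in 1:3) for (b in setdiff(BASES, v[p])) {
      w <- v; w[p] <- b
      alt <- code[[chars_to_seq(w)]]
      if (alt == code[[cd]]) syn_cnt[cd, p] <- syn_cnt[cd, p] + 1L
      else if (alt != "*")
        nonstop_nonsyn_cnt[cd, p] <- nonstop_nonsyn_cnt[cd, p] + 1L
    }
    # changes to stop codons count as nonsynonymous potential
    syn_sites[[cd]] <- if (code[[cd]] == "*") NA_real_ else sum(syn_cnt[cd, ]) / 3
  }
  the_codon_cache$tables <- list(aa = aa, syn_sites = syn_sites, code = code,
                                 syn_cnt = syn_cnt,
                                 nonstop_nonsyn_cnt = nonstop_nonsyn_cnt)
  the_codon_cache$tables
}

#' Split a sequence string into codons
#' @param s DNA string with length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(s) {
  if (nchar(s) %% 3 != 0) stop2("sequence length not divisible by 3")
  substring(s, seq(1, nchar(s), by = 3), seq(3, nchar(s), by = 3))
}

codon_is_clean <- function(codon, code) {
  grepl("^[ACGT]{3}$", codon) && code[[codon]] != "*"
}

# pathway-averaged (syn, nonsyn) difference counts for one codon pair.
# Enumerates the d! orderings of the d differing positions; a pathway whose
# intermediate codon is a stop is excluded; if every pathway is blocked the
# average falls back to all pathways (stop steps counted as nonsynonymous).
codon_pair_diffs <- function(a, b, code) {
  if (a == b) return(c(syn = 0, nonsyn = 0))
  key <- paste0(a, b)
  hit <- get0(key, envir = the_codon_cache, ifnotfound = NULL)
  if (!is.null(hit)) return(hit)
  va <- seq_to_chars(a); vb <- seq_to_chars(b)
  pos <- which(va != vb)
  perms <- list()
  permute <- function(p, acc) {
    if (!length(p)) { perms[[length(perms) + 1L]] <<- acc; return(invisible()) }
    for (i in seq_along(p)) permute(p[-i], c(acc, p[i]))
  }
  permute(pos, integer(0))
  path_counts <- function(include_stops) {
    tot <- c(syn = 0, nonsyn = 0); used <- 0L
    for (ord in perms) {
      cur <- va
      steps <- c(syn = 0, nonsyn = 0)
      blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- vb[p]
        aa1 <- code[[chars_to_seq(cur)]]; aa2 <- code[[chars_to_seq(nxt)]]
        if (aa2 == "*" && !include_stops &&
            !identical(chars_to_seq(nxt), b)) { blocked <- TRUE; break }
        if (aa1 == aa2 && aa1 != "*") steps["syn"] <- steps["syn"] + 1
        else steps["nonsyn"] <- steps["nonsyn"] + 1
        cur <- nxt
      }
      if (!blocked) { tot <- tot + steps; used <- used + 1L }
    }
    list(tot = tot, used = used)
  }
  pc <- path_counts(include_stops = FALSE)
  if (pc$used == 0L) pc <- path_counts(include_stops = TRUE)
  out <- pc$tot / pc$used
  assign(key, out, envir = the_codon_cache)
  out
}

#' Nei-Gojobori (1986) pairwise rates for two codon sequences
#'
#' Codons containing gaps or N, and stop codons, are excluded pairwise.
#' Potential synonymous sites per codon come from enumerating all nine
#' single-base changes (changes to stop codons are nonsynonymous
#' potential); S and N are averaged over the two sequences. Observed
#' differences are apportioned by averaging over all minimal mutational
#' pathways, excluding pathways through stop codons. Proportions are
#' Jukes-Cantor corrected; a proportion of 3/4 or more leaves the rate
#' undefined (NA, flagged by the caller).
#'
#' @param codons_a,codons_b character vectors of codons (equal length), or
#'   strings with length divisible by 3
#' @return one-row data frame: `s_sites`, `n_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `ps`, `pn`, `ds`, `dn`, `n_codons_compared`
#' @export
ng86_pair <- function(codons_a, codons_b) {
  if (length(codons_a) == 1 && nchar(codons_a[1]) > 3)
    codons_a <- split_codons(codons_a)
  if (length(codons_b) == 1 && nchar(codons_b[1]) > 3)
    codons_b <- split_codons(codons_b)
  if (length(codons_a) != length(codons_b))
    stop2("codon sequences differ in length")
  tb <- the_codon_tables()
  code <- tb$code
  ok <- vapply(seq_along(codons_a), function(i)
    codon_is_clean(codons_a[i], code) && codon_is_clean(codons_b[i], code),
    logical(1))
  a <- codons_a[ok]; b <- codons_b[ok]
  nc <- length(a)
  if (nc == 0) {
    return(data.frame(s_sites = NA_real_, n_sites = NA_real_,
                      syn_diffs = NA_real_, nonsyn_diffs = NA_real_,
                      ps = NA_real_, pn = NA_real_, ds = NA_real_,
                      dn = NA_real_, n_codons_compared = 0L))
  }
  S <- (sum(tb$syn_sites[a]) + sum(tb$syn_sites[b])) / 2
  N <- 3 * nc - S
  sd_ <- nd_ <- 0
  diff <- which(a != b)
  for (i in diff) {
    d <- codon_pair_diffs(a[i], b[i], code)
    sd_ <- sd_ + d[["syn"]]; nd_ <- nd_ + d[["nonsyn"]]
  }
  ps <- if (S > 0) sd_ / S else NA_real_
  pn <- if (N > 0) nd_ / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  data.frame(s_sites = S, n_sites = N, syn_diffs = sd_, nonsyn_diffs = nd_,
             ps = ps, pn = pn, ds = jc(ps), dn = jc(pn),
             n_codons_compared = nc)
}

#' Per-gene rate estimate over all sequence pairs
#'
#' Applies [ng86_pair()] to every unordered pair of rows, averages sites,
#' difference counts and corrected rates over pairs with defined values,
#' and reports omega = mean dN / mean dS. Genes with dS = 0 and dN > 0 get
#' an undefined omega and the flag `nonsynonymous-only`; genes with no
#' variation at all are flagged `invariant`.
#'
#' @param aln codon `alignment_matrix` (columns divisible by 3)
#' @param gene gene name carried into the output
#' @return one-row data frame (`gene_rate_estimate`)
#' @export
gene_rates <- function(aln, gene = "gene") {
  if (aln_length(aln) %% 3 != 0)
    stop2("codon alignment length not divisible by 3")
  rows <- apply(aln$mat, 1, paste, collapse = "")
  cod <- lapply(rows, function(s) {
    v <- split_codons(s)
    v[grepl("-", v, fixed = TRUE)] <- "---"   # partial-gap codons excluded
    v
  })
  prs <- pair_index(length(cod))
  ests <- lapply(seq_len(ncol(prs)), function(k)
    ng86_pair(cod[[prs[1, k]]], cod[[prs[2, k]]]))
  est <- do.call(rbind, ests)
  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  ds <- mean_def(est$ds); dn <- mean_def(est$dn)
  flag <- ""
  omega <- NA_real_
  if (!is.na(ds) && !is.na(dn)) {
    if (ds == 0 && dn == 0) flag <- "invariant"
    else if (ds == 0 && dn > 0) flag <- "nonsynonymous-only"
    else if (ds > 0 && dn == 0) { flag <- "synonymous-only"; omega <- 0 }
    else omega <- dn / ds
  }
  data.frame(gene = gene,
             s_sites = mean_def(est$s_sites), n_sites = mean_def(est$n_sites),
             syn_diffs = mean_def(est$syn_diffs),
             nonsyn_diffs = mean_def(est$nonsyn_diffs),
             ds = ds, dn = dn, omega = omega,
             n_pairs = sum(!is.na(est$ds) | !is.na(est$dn)),
             flag = flag, stringsAsFactors = FALSE)
}

#' Rate table for every gene in a set
#' @param set a `gene_alignment_set`
#' @return data frame with one [gene_rates()] row per gene
#' @export
gene_rates_table <- function(set) {
  do.call(rbind, lapply(names(set$alignments), function(g)
    gene_rates(set$alignments[[g]], gene = g)))
}

#' Assign protein-coding genes to the nine conventional functional groups
#'
#' Deterministic assignment by gene-name prefix using the editable table
#' shipped in `extdata/functional_groups.tsv`: photosystem I (psa),
#' photosystem II (psb), cytochrome b6f (pet), ATP synthase (atp), NADH
#' dehydrogenase (ndh), RuBisCO (rbcL), RNA polymerase (rpo), ribosomal
#' proteins (rps/rpl), and other/unknown for everything else (ycf, matK,
#' clpP, ccsA, cemA, accD, infA, ...), with a logged note for names not
#' matching any rule.
#'
#' @param genes character vector of normalized gene names
#' @return data frame (`group`, `gene`); all nine groups appear in the
#'   factor order even when empty
#' @export
classify_functional_groups <- function(genes) {
  path <- system.file("extdata", "functional_groups.tsv", package = "plastdiv")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  groups <- unique(tab$group)
  assign1 <- function(g) {
    exact <- tab$group[tab$match == g & tab$type == "exact"]
    if (length(exact)) return(exact[1])
    pref <- tab[tab$type == "prefix", ]
    hit <- pref$group[startsWith(g, pref$match)]
    if (length(hit)) return(hit[1])
    message("gene ", g, " matched no functional-group rule; assigned to other")
    "other"
  }
  out <- data.frame(group = factor(vapply(genes, assign1, ""), levels = groups),
                    gene = genes, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-functional-group substitution rates
#'
#' For each group the member codon alignments are concatenated in
#' alphabetical order and [gene_rates()] applied to the concatenation; the
#' mean and standard deviation of the per-gene estimates within the group
#' are reported alongside.
#'
#' @param estimates per-gene table from [gene_rates_table()]
#' @param groups assignment from [classify_functional_groups()]
#' @param set the `gene_alignment_set` the estimates came from
#' @return data frame with one row per non-empty group
#' @export
group_rates <- function(estimates, groups, set) {
  stray <- setdiff(estimates$gene, groups$gene)
  if (length(stray))
    stop2("gene(s) in no functional group: ", paste(stray, collapse = ", "))
  out <- list()
  for (grp in levels(groups$group)) {
    members <- sort(intersect(groups$gene[groups$group == grp],
                              names(set$alignments)))
    if (!length(members)) next
    taxa <- set$taxa
    big <- do.call(cbind, lapply(set$alignments[members], function(a)
      a$mat[taxa, , drop = FALSE]))
    rows <- apply(big, 1, paste, collapse = "")
    names(rows) <- taxa
    conc <- gene_rates(alignment_matrix(rows), gene = grp)
    sub <- estimates[estimates$gene %in% members, ]
    out[[length(out) + 1L]] <- data.frame(
      group = grp, n_genes = length(members),
      dn_concat = conc$dn, ds_concat = conc$ds, omega_concat = conc$omega,
      dn_mean = mean(sub$dn, na.rm = TRUE),
      dn_sd = stats::sd(sub$dn[!is.na(sub$dn)]),
      ds_mean = mean(sub$ds, na.rm = TRUE),
      ds_sd = stats::sd(sub$ds[!is.na(sub$ds)]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
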