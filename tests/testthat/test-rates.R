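# NG86 counting method: sites, pathway-averaged differences, corrections

test_that("the TTT/TTC worked case matches the hand enumeration", {
  # TTT (Phe): of the nine single-base changes only TTT->TTC is synonymous,
  # so 1/3 synonymous site; same for TTC. S = 1/3, N = 8/3; the single
  # observed difference is synonymous, pS = 1/(1/3) = 3 >= 3/4 so the
  # Jukes-Cantor correction is undefined for this one-codon pair.
  res <- ng86_pair("TTT", "TTC")
  expect_equal(res$s_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(res$n_sites, 8 / 3, tolerance = 1e-12)
  expect_equal(res$syn_diffs, 1)
  expect_equal(res$nonsyn_diffs, 0)
  expect_equal(res$ps, 3)
  expect_true(is.na(res$ds))
  expect_equal(res$pn, 0)
  expect_equal(res$dn, 0)
})

test_that("identical sequences give zero rates", {
  res <- ng86_pair("ATGAAACCC", "ATGAAACCC")
  expect_equal(res$ds, 0)
  expect_equal(res$dn, 0)
  expect_equal(res$syn_diffs, 0)
})

test_that("sites are conserved and the pair statistic is symmetric", {
  set.seed(51)
  for (rep in 1:20) {
    nc <- sample(3:20, 1)
    a <- replicate(nc, random_codon())
    b <- vapply(a, function(cd) {
      if (runif(1) < 0.5) return(cd)
      repeat {
        v <- strsplit(cd, "")[[1]]
        k <- sample(3, sample(1:3, 1))
        v[k] <- sample(c("A", "C", "G", "T"), length(k), replace = TRUE)
        out <- paste(v, collapse = "")
        if (oracle_translate(out) != "*") return(out)
      }
    }, character(1))
    ab <- ng86_pair(a, b)
    ba <- ng86_pair(b, a)
    expect_equal(ab$s_sites + ab$n_sites, 3 * ab$n_codons_compared,
                 tolerance = 1e-9)
    expect_equal(ab[, c("s_sites", "syn_diffs", "nonsyn_diffs", "ds", "dn")],
                 ba[, c("s_sites", "syn_diffs", "nonsyn_diffs", "ds", "dn")],
                 tolerance = 1e-12)
  }
})

test_that("pathway-averaged counts match exhaustive enumeration", {
  set.seed(52)
  for (rep in 1:40) {
    a <- random_codon()
    b <- random_codon()
    got <- ng86_pair(a, b)
    oracle <- oracle_pair_diffs(a, b)
    expect_equal(got$syn_diffs, unname(oracle["syn"]), tolerance = 1e-12)
    expect_equal(got$nonsyn_diffs, unname(oracle["nonsyn"]), tolerance = 1e-12)
  }
  # the spec's named two-pathway case: one codon with two differences
  got <- ng86_pair(c("TTT", "GGG"), c("TTA", "GGG"))
  expect_equal(got$syn_diffs + got$nonsyn_diffs, 1)
})

test_that("codons with gaps, N or stops are excluded pairwise", {
  a <- c("ATG", "---", "AAN", "TAA", "CCC")
  b <- c("ATG", "AAA", "AAA", "AAA", "CCC")
  res <- ng86_pair(a, b)
  expect_equal(res$n_codons_compared, 2L)
  expect_error(ng86_pair(c("ATG"), c("ATG", "AAA")), "length")
})

test_that("the correction approaches the proportion for small p", {
  set.seed(53)
  # long nearly-identical sequences: d ~ p with < 1% relative error
  a <- replicate(2000, random_codon())
  b <- a
  idx <- sample(2000, 12)
  for (i in idx) {
    repeat {
      v <- strsplit(a[i], "")[[1]]
      v[3] <- sample(setdiff(c("A", "C", "G", "T"), v[3]), 1)
      out <- paste(v, collapse = "")
      if (oracle_translate(out) != "*") { b[i] <- out; break }
    }
  }
  res <- ng86_pair(a, b)
  expect_lt(res$ps, 0.01 + 1e-9)
  if (res$ps > 0) expect_lt(abs(res$ds - res$ps) / res$ps, 0.01)
})

test_that("gene_rates flags invariant and one-sided genes", {
  same <- alignment_matrix(c(a = "ATGAAACCCTTT", b = "ATGAAACCCTTT",
                             d = "ATGAAACCCTTT"))
  res <- gene_rates(same)
  expect_equal(res$ds, 0)
  expect_equal(res$dn, 0)
  expect_true(is.na(res$omega))
  expect_equal(res$flag, "invariant")
  # a single synonymous difference: dN = 0, dS > 0
  syn <- alignment_matrix(c(a = "ATGAAACCCCTT", b = "ATGAAACCGCTT",
                            d = "ATGAAACCCCTT"))
  res2 <- gene_rates(syn)
  expect_equal(res2$dn, 0)
  expect_gt(res2$ds, 0)
  expect_equal(res2$omega, 0)
  # a single nonsynonymous difference: omega undefined, flagged
  non <- alignment_matrix(c(a = "ATGAAACCCCTT", b = "ATGAACCCCCTT",
                            d = "ATGAAACCCCTT"))
  res3 <- gene_rates(non)
  expect_equal(res3$ds, 0)
  expect_gt(res3$dn, 0)
  expect_true(is.na(res3$omega))
  expect_equal(res3$flag, "nonsynonymous-only")
})

test_that("functional groups follow the shipped prefix table", {
  grp <- classify_functional_groups(c("rpoC2", "ycf1", "psbA", "rps12",
                                      "rbcL", "weird9"))
  lookup <- stats::setNames(as.character(grp$group), grp$gene)
  expect_equal(unname(lookup["rpoC2"]), "rna_polymerase")
  expect_equal(unname(lookup["ycf1"]), "other")
  expect_equal(unname(lookup["psbA"]), "photosystem_II")
  expect_equal(unname(lookup["rps12"]), "ribosomal_protein")
  expect_equal(unname(lookup["rbcL"]), "rubisco")
  expect_message(g2 <- classify_functional_groups("weird9"), "weird9")
  expect_equal(as.character(g2$group), "other")
})

test_that("the full plastome gene list fills all nine groups", {
  plan <- default_genome_plan()
  pcg <- plan$genes$name[plan$genes$kind == "PCG"]
  grp <- classify_functional_groups(pcg)
  expect_equal(nlevels(grp$group), 9L)
  expect_true(all(table(grp$group) > 0))
})

test_that("group concatenation equals rates on the manually joined alignment", {
  a1 <- alignment_matrix(c(x = "ATGAAACCC", y = "ATGAAGCCC"))
  a2 <- alignment_matrix(c(x = "ATGTTTGGG", y = "ATGTTCGGG"))
  set <- structure(list(alignments = list(ndhA = a1, ndhB = a2),
                        taxa = c("x", "y"), flagged = data.frame()),
                   class = "gene_alignment_set")
  est <- gene_rates_table(set)
  groups <- classify_functional_groups(est$gene)
  gr <- group_rates(est, groups, set)
  joined <- alignment_matrix(c(x = "ATGAAACCCATGTTTGGG",
                               y = "ATGAAGCCCATGTTCGGG"))
  manual <- gene_rates(joined)
  expect_equal(gr$ds_concat[gr$group == "ndh_dehydrogenase"], manual$ds)
  expect_equal(gr$dn_concat[gr$group == "ndh_dehydrogenase"], manual$dn)
  # a gene missing from every group is a hard error
  bad_groups <- groups[groups$gene != "ndhA", ]
  expect_error(group_rates(est, bad_groups, set), "ndhA")
})

test_that("omega is recovered on long simulated genes", {
  # 1500-codon genes under omega 0.2, with theta chosen so the synonymous
  # sites (which carry most of the thinned coding rate) diverge at the 0.05
  # scale the corrected estimator is designed for
  oms <- c()
  for (s in 1:6) {
    cfg <- simulation_config(seed = 300 + s, genome_plan = long_gene_plan(),
                             n_taxa = 5, theta = 0.02, omega_true = 0.2,
                             region_rate_multipliers =
                               c(exon = 1, intron = 1, IGS = 1),
                             n_hotspot_igs = 0, indel_rate = 0)
    sim <- simulate_plastomes(cfg)
    est <- gene_rates_table(extract_codon_alignments(sim$genomes))
    oms <- c(oms, est$omega)
  }
  se <- stats::sd(oms) / sqrt(length(oms))
  expect_lt(abs(mean(oms) - 0.2), 3 * se)
})
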