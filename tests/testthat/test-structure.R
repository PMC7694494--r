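# quadripartite structure detection, junctions, genome summaries

test_that("planted IRs are recovered exactly", {
  for (s in 1:5) {
    anc <- simulate_ancestor(fast_config(seed = 100 + s))
    q <- find_inverted_repeats(anc$genome, min_len = 1000)
    expect_true(q$found)
    n <- q$genome_length
    expect_equal(unname(q$ira) %% n, unname(anc$structure$ira) %% n)
    expect_equal(unname(q$irb) %% n, unname(anc$structure$irb) %% n)
    expect_equal(q$ir_len, anc$structure$ir_len)
  }
})

test_that("a random sequence without a planted repeat yields a no-IR result", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  q <- find_inverted_repeats(seq, min_len = 1000)
  expect_false(q$found)
})

test_that("region lengths partition the genome", {
  for (s in c(7, 8)) {
    anc <- simulate_ancestor(fast_config(seed = s))
    q <- find_inverted_repeats(anc$genome, min_len = 1000)
    expect_equal(q$lsc_len + q$ssc_len + 2 * q$ir_len, q$genome_length)
    expect_true(q$lsc_len > q$ssc_len)
  }
})

test_that("the IR copies are exact reverse complements", {
  anc <- simulate_ancestor(fast_config(seed = 9))
  q <- find_inverted_repeats(anc$genome, min_len = 1000)
  n <- q$genome_length
  sv <- strsplit(anc$genome$seq, "")[[1]]
  get_region <- function(iv) paste(sv[(iv[1]:(iv[2] - 1)) %% n + 1],
                                   collapse = "")
  rc <- function(s) paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])),
                          collapse = "")
  expect_identical(rc(get_region(q$irb)), get_region(q$ira))
})

test_that("detection is invariant to rotation and reverse complement", {
  anc <- simulate_ancestor(fast_config(seed = 10))
  seq <- anc$genome$seq
  n <- nchar(seq)
  q0 <- find_inverted_repeats(seq, min_len = 1000)
  for (off in c(137, n %/% 3)) {
    rot <- paste0(substring(seq, off + 1, n), substring(seq, 1, off))
    q <- find_inverted_repeats(rot, min_len = 1000)
    expect_equal(q$ir_len, q0$ir_len)
    expect_equal(q$lsc_len, q0$lsc_len)
    expect_equal(q$ssc_len, q0$ssc_len)
  }
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(seq, "")[[1]])),
              collapse = "")
  qr <- find_inverted_repeats(rc, min_len = 1000)
  expect_equal(qr$ir_len, q0$ir_len)
  expect_equal(qr$lsc_len, q0$lsc_len)
})

test_that("detection agrees with the quadratic brute-force oracle", {
  set.seed(7)
  for (rep in 1:6) {
    n <- 1200
    sv <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ir_len <- sample(60:120, 1)
    a <- sample(100:300, 1)
    b <- sample(600:900, 1)
    ir <- sample(c("A", "C", "G", "T"), ir_len, replace = TRUE)
    sv[a:(a + ir_len - 1)] <- ir
    sv[b:(b + ir_len - 1)] <- rev(chartr("ACGT", "TGCA", ir))
    seq <- paste(sv, collapse = "")
    oracle <- brute_ir(seq, min_len = 50)
    q <- find_inverted_repeats(seq, min_len = 50)
    expect_true(q$found)
    expect_equal(q$ir_len, oracle$len)
    starts <- sort(c(q$ira[1] %% n, q$irb[1] %% n))
    expect_equal(starts[1], oracle$start)
  }
})

test_that("genome summaries report the planted architecture", {
  anc <- simulate_ancestor(fast_config(seed = 12))
  q <- find_inverted_repeats(anc$genome, min_len = 1000)
  s <- summarize_genome(anc$genome, q)
  expect_equal(s$genome_size, s$lsc_len + s$ssc_len + 2 * s$ir_len)
  expect_equal(s$total_genes, 17L)
  expect_equal(s$unique_genes, 14L)
  expect_equal(s$dup_in_ir, 3L)
  expect_true(s$unique_genes <= s$total_genes)
  expect_equal(s$coding_len, s$pcg_len + s$trna_len + s$rrna_len)
})

test_that("GC percentages follow the composition, rounded half-up", {
  g <- annotated_genome("allA", strrep("A", 4000))
  q <- find_inverted_repeats(g, min_len = 1000)
  s <- summarize_genome(g, q)
  expect_equal(s$gc_total, 0)
  # half-up rounding at the printed precision: 38.25 -> 38.3
  expect_equal(plastdiv:::round_half_up(38.25, 1), 38.3)
  expect_equal(plastdiv:::round_half_up(43.44, 1), 43.4)
})

test_that("junction table reports planted spanning genes with their overlap", {
  # toy genome: LSC 5000, IR 1500, SSC 2000; a gene spans JSB by 120 bp
  set.seed(33)
  L <- 5000L; I <- 1500L; S <- 2000L
  ira <- sample(c("A", "C", "G", "T"), I, replace = TRUE)
  lsc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ssc <- sample(c("A", "C", "G", "T"), S, replace = TRUE)
  irb <- rev(chartr("ACGT", "TGCA", ira))
  seq <- paste(c(lsc, irb, ssc, ira), collapse = "")
  jsb <- L + I  # 0-based first SSC base
  feats <- list(
    gene_feature("ndhF", "PCG", "+", matrix(c(jsb - 200L, jsb + 120L),
                                            ncol = 2)),
    gene_feature("psbA", "PCG", "+", matrix(c(100L, 400L), ncol = 2)))
  g <- annotated_genome("toy", seq, feats)
  q <- find_inverted_repeats(g, min_len = 1000)
  jt <- junction_table(list(list(genome = g, structure = q)))
  row <- jt[jt$junction == "JSB", ]
  expect_equal(row$spanning_gene, "ndhF")
  expect_equal(row$overlap_bp, 120L)
  # a gene exactly abutting a junction overlaps by 0
  feats2 <- list(gene_feature("rpl2", "PCG", "+",
                              matrix(c(jsb, jsb + 300L), ncol = 2)))
  g2 <- annotated_genome("toy2", seq, feats2)
  jt2 <- junction_table(list(list(genome = g2, structure = q)))
  expect_equal(jt2$overlap_bp[jt2$junction == "JSB"], 0L)
})

test_that("genomes lacking features still get junction positions", {
  anc <- simulate_ancestor(fast_config(seed = 14))
  g <- annotated_genome("bare", anc$genome$seq)
  q <- find_inverted_repeats(g, min_len = 1000)
  jt <- junction_table(list(list(genome = g, structure = q)))
  expect_equal(nrow(jt), 4L)
  expect_true(all(is.na(jt$gene_left)))
})
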