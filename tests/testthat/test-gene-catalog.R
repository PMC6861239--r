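test_that("isoform merge and strand-aware extension follow the window rules", {
  gm <- data.frame(
    symbol = c("GENE1", "GENE1", "GENE2", "GENE3", "GENEX", "GENEU"),
    chrom = c("1", "1", "2", "2", "X", "3"),
    strand = c("+", "+", "+", "-", "+", "."),
    start = c(1000L, 1500L, 1000000L, 1000000L, 500L, 1000000L),
    end = c(2000L, 3000L, 1010000L, 1010000L, 900L, 1010000L),
    stringsAsFactors = FALSE)
  reg <- merge_and_extend(gm)
  expect_false("GENEX" %in% reg$symbol)   # non-autosomal chromosome removed

  g1 <- reg[reg$symbol == "GENE1", ]
  expect_equal(c(g1$start, g1$end), c(1000L, 3000L))
  expect_equal(c(g1$ext_start, g1$ext_end), c(1L, 43000L))  # clipped at 1

  g2 <- reg[reg$symbol == "GENE2", ]
  expect_equal(c(g2$ext_start, g2$ext_end), c(890000L, 1050000L))

  g3 <- reg[reg$symbol == "GENE3", ]  # minus strand: mirrored extension
  expect_equal(c(g3$ext_start, g3$ext_end), c(960000L, 1120000L))

  gu <- reg[reg$symbol == "GENEU", ]  # unknown strand: symmetric max window
  expect_equal(c(gu$ext_start, gu$ext_end), c(890000L, 1120000L))
})

test_that("invalid transcripts are rejected and mapping ignores isoform order", {
  gm <- data.frame(symbol = "BAD", chrom = "1", strand = "+",
                   start = 500L, end = 100L, stringsAsFactors = FALSE)
  expect_message(reg <- merge_and_extend(gm), "rejected")
  expect_equal(nrow(reg), 0L)

  gm2 <- data.frame(symbol = "G", chrom = "1", strand = "+",
                    start = c(1000L, 5000L, 200L), end = c(2000L, 9000L, 700L))
  perm <- gm2[c(3, 1, 2), ]
  expect_equal(merge_and_extend(gm2), merge_and_extend(perm))
})

test_that("SNP-to-gene mapping enforces the strict p filter and containment", {
  regions <- merge_and_extend(data.frame(
    symbol = "GENE2", chrom = "2", strand = "+",
    start = 1000000L, end = 1010000L))  # extended [890000, 1050000]
  snps <- data.frame(
    rsid = c("rs_in", "rs_out", "rs_border", "rs_weak", "rs_offchrom"),
    chrom = c("2", "2", "2", "2", "9"),
    pos = c(895000L, 889999L, 890000L, 895001L, 895000L),
    pval = c(1e-9, 1e-9, 1e-9, 5e-8, 1e-9),
    stringsAsFactors = FALSE)
  res <- map_snps_to_genes(snps, regions)
  expect_equal(res$genes$symbol, "GENE2")
  hits <- strsplit(res$genes$snps, ",")[[1]]
  expect_setequal(hits, c("rs_in", "rs_border"))  # closed interval start
  expect_false("rs_weak" %in% hits)               # p = 5e-8 excluded (strict <)
  expect_equal(res$skipped_snps, 1L)              # chromosome 9 has no models
})

test_that("region overlap enrichment matches the exact Fisher oracle", {
  # query: 100 SNPs, 10 inside [1, 1000]; background: 1000 SNPs, 10 inside
  intervals <- data.frame(chrom = "1", start = 1L, end = 1000L)
  qpos <- c(seq(10L, 910L, by = 100L), seq(2000L, 2000L + 89L * 10L, by = 10L))
  bpos <- c(seq(10L, 910L, by = 100L), seq(2000L, 2000L + 989L * 10L, by = 10L))
  q <- data.frame(chrom = "1", pos = qpos)
  b <- data.frame(chrom = "1", pos = bpos)
  res <- region_overlap_enrichment(q, b, intervals)
  expect_equal(unname(res$table[, "query"]), c(10L, 90L))
  expect_equal(unname(res$table[, "background"]), c(10L, 990L))
  expect_equal(res$odds_ratio, (10 * 990) / (90 * 10))
  expect_equal(res$p_value, oracle_fisher_two_sided(10L, 10L, 90L, 990L),
               tolerance = 1e-9)

  # identical overlap rates -> OR 1
  res_eq <- region_overlap_enrichment(q, q, intervals)
  expect_equal(res_eq$odds_ratio, 1)

  expect_error(region_overlap_enrichment(q[0, ], b, intervals), "empty query")

  # zero margin: nothing overlaps anywhere
  far <- data.frame(chrom = "1", pos = c(5000L, 6000L))
  res_deg <- region_overlap_enrichment(far, far, intervals)
  expect_true(res_deg$degenerate)
  expect_true(is.nan(res_deg$odds_ratio))
  expect_equal(res_deg$p_value, 1)
})

test_that("ORA p-values equal the hypergeometric tail oracle", {
  universe <- sprintf("U%03d", 1:100)
  query <- universe[1:10]
  libs <- list(SET_A = c(universe[1:5], universe[51:55]),  # overlap 5 of 10
               SET_B = universe[90:99])                    # overlap 0
  res <- ora_test(query, libs, universe = universe)
  expect_equal(res$p[res$set == "SET_A"],
               oracle_hyper_upper(5L, 100L, 10L, 10L), tolerance = 1e-12)
  expect_equal(res$p[res$set == "SET_B"],
               oracle_hyper_upper(0L, 100L, 10L, 10L), tolerance = 1e-12)

  # random tables against the oracle (N <= 60)
  set.seed(42)
  for (i in 1:25) {
    N <- sample(10:60, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    uni <- sprintf("V%03d", 1:N)
    q <- sample(uni, n); s <- sample(uni, K)
    r <- ora_test(q, list(S = s), universe = uni)
    k <- length(intersect(q, s))
    expect_equal(r$p, oracle_hyper_upper(k, N, K, n), tolerance = 1e-12)
  }
})

test_that("BH behavior: identity at m = 1, monotone adjusted p", {
  universe <- sprintf("U%03d", 1:50)
  query <- universe[1:8]
  one <- ora_test(query, list(ONLY = query), universe = universe)
  expect_equal(one$p_adj, one$p)

  libs <- lapply(1:6, function(i) sample(universe, 10))
  names(libs) <- paste0("S", 1:6)
  res <- ora_test(query, libs, universe = universe)
  expect_true(all(res$p_adj >= res$p))
  o <- order(res$p)
  expect_true(all(diff(res$p_adj[o]) >= -1e-12))
})

test_that("combine_sources tracks source flags and Venn regions", {
  expect_message(
    cs <- combine_sources(c("A", "B", "B"), c("B", "C"), c("C", "D")),
    "duplicate")
  expect_equal(cs$genes$symbol, c("A", "B", "C", "D"))
  b <- cs$genes[cs$genes$symbol == "B", ]
  expect_true(b$catalog && b$sumstats && !b$textmining)
  expect_equal(b$sources, "catalog,sumstats")
  expect_equal(sum(cs$venn), nrow(cs$genes))
  expect_equal(unname(cs$venn[c("C", "CS", "ST", "T")]), c(1L, 1L, 1L, 1L))

  expect_warning(empty <- combine_sources(character(0), character(0),
                                          character(0)), "empty")
  expect_equal(nrow(empty$genes), 0L)
})

test_that("the enrichment filter retains exactly the genes in significant sets", {
  universe <- sprintf("U%03d", 1:80)
  gwas <- universe[1:10]
  txt <- c(universe[11:12], "OFFUNIVERSE")
  cs <- combine_sources(gwas, character(0), txt)
  libs <- list(GOOD = universe[1:12],       # strongly overlaps the GWAS genes
               BAD = universe[60:80])       # no overlap
  fs <- ora_filter(cs, libs, universe = universe)
  expect_true("GOOD" %in% fs$significant_sets)
  expect_false("BAD" %in% fs$significant_sets)
  ret <- disease_genes(fs)
  # every retained gene is in >= 1 significant set (spec invariant)
  sig_members <- unique(unlist(libs[fs$significant_sets]))
  expect_true(all(ret %in% sig_members))
  # union scope keeps text-mining genes that land in a significant set
  expect_true(all(c("U011", "U012") %in% ret))
  # gwas_only scope drops them
  fs2 <- ora_filter(cs, libs, universe = universe, scope = "gwas_only")
  expect_false(any(c("U011", "U012") %in% disease_genes(fs2)))
})

test_that("GMT round-trips through the reader", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tA\tB\tC", "SET2\tdesc\tB\tD"), path)
  gmt <- read_gmt(path)
  expect_equal(gmt, list(SET1 = c("A", "B", "C"), SET2 = c("B", "D")))
})
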