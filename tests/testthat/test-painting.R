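write_toy_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr01,length=300000>",
    "##contig=<ID=chr02,length=300000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "offspring", "parent_a", "parent_b"), collapse = "\t")
  )
  writeLines(c(header, rows), path)
}

vrow <- function(chrom, pos, ref, alt, qual, g_off, g_pa, g_pb) {
  paste(chrom, pos, ".", ref, alt, qual, "PASS", ".", "GT",
        g_off, g_pa, g_pb, sep = "\t")
}

test_that("QUAL filter is inclusive at 30 and drops indels/multiallelics", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c(
    vrow("chr01", 100, "A", "T", 60, "0/0", "0/0", "1/1"),
    vrow("chr01", 200, "C", "G", 29, "1/1", "0/0", "1/1"),   # below threshold
    vrow("chr01", 300, "G", "A", 30, "1/1", "0/0", "1/1"),   # boundary: kept
    vrow("chr01", 400, "T", "C", 99, "0/0", "1/1", "0/0"),
    vrow("chr01", 500, "A", "AT", 60, "0/0", "0/0", "1/1"),  # indel: dropped
    vrow("chr01", 600, "A", "T,G", 60, "0/0", "1/1", "2/2"), # multiallelic
    vrow("chr01", 700, "A", "T", 60, "0/1", "0/0", "1/1")    # het offspring
  ))
  kept <- filter_sites(path, min_qual = 30)
  expect_setequal(kept$pos, c(100, 300, 400, 700))
  expect_true(is.na(kept$off[kept$pos == 700]))  # het resolves to NA
  all_snps <- filter_sites(path, min_qual = 0)
  expect_setequal(all_snps$pos, c(100, 200, 300, 400, 700))
  # toy fixture of 6 SNP records, one below QUAL 30 -> 5 retained
  expect_equal(nrow(all_snps) + 1L, 6L)  # (indel & multiallelic never count)
  expect_error(filter_sites(path, offspring = "kid"), "available")
})

test_that("parental-origin classification follows the allele-matching rules", {
  expect_equal(classify_snps(off = "A", pa = "A", pb = "T"), "parent_a")
  expect_equal(classify_snps(off = "T", pa = "A", pb = "T"), "parent_b")
  expect_equal(classify_snps(off = "G", pa = "A", pb = "T"), "other")
  expect_equal(classify_snps(off = "A", pa = "A", pb = "A"), NA_character_)
  expect_equal(classify_snps(off = NA, pa = "A", pb = "T"), NA_character_)
  # offspring matching both identical parents is uninformative, matching
  # neither identical parent is "other"
  expect_equal(classify_snps(off = "C", pa = "A", pb = "A"), "other")
})

test_that("windows are anchored at 1 with ceiling assignment and tie -> other", {
  sites <- data.frame(
    chrom = "chr01",
    pos = c(50000, 50001, 10, 20, 30, 120000, 130000),
    class = c("parent_a", "parent_b", "parent_a", "parent_a", "parent_b",
              "parent_a", "parent_b"),
    stringsAsFactors = FALSE
  )
  bl <- window_paint(sites, c(chr01 = 250001), w = 50000)
  expect_equal(nrow(bl), 6L)                      # ceil(250001 / 50000)
  expect_equal(bl$start[6], 250001)
  expect_equal(bl$end[6], 300000)
  # pos 50000 stays in window 1, pos 50001 moves to window 2
  expect_equal(bl$n_parent_a[1], 3L)  # 10, 20, 50000... minus 50001
  expect_equal(bl$n_parent_b[2], 1L)
  # window 1: A=3 (10,20,50000), B=1 (30) -> dominant parent_a
  expect_equal(bl$dominant[1], "parent_a")
  # window 3 (100001-150000): one of each -> tie -> other
  expect_equal(bl$dominant[3], "other")
  # empty windows are missing
  expect_equal(bl$dominant[4], "missing")
})

test_that("composition reproduces published count tables", {
  all_snps <- composition(c(parent_a = 515698, parent_b = 65426,
                            other = 9540))
  expect_equal(all_snps$pct, c(87, 11, 2))
  expect_equal(attr(all_snps, "total"), 590664)
  w50 <- composition(c(parent_a = 4406, parent_b = 1791, other = 1256))
  expect_equal(w50$pct, c(59, 24, 17))
  expect_equal(attr(w50, "total"), 7453)
  w100 <- composition(c(parent_a = 2328, parent_b = 832, other = 564))
  expect_equal(w100$pct, c(63, 22, 15))
  expect_equal(attr(w100, "total"), 3724)
  uniform <- composition(c(parent_a = 1, parent_b = 1, other = 1))
  expect_equal(uniform$pct, c(33, 33, 33))
})

test_that("window counts sum to non-missing windows; site counts to classified", {
  cfg <- sim_config(n_chrom = 3L, chrom_len = 300000L, seed = 61L,
                    mean_segment_len = 120000, min_segment_len = 50000)
  ds <- simulate_dataset(cfg, withr::local_tempdir())
  sites <- classify_snps(filter_sites(ds$paths$vcf))
  lens <- stats::setNames(Biostrings::width(ds$founders$genomes$A),
                          names(ds$founders$genomes$A))
  bl <- window_paint(sites, lens, 50000)
  comp_w <- composition(bl)
  expect_equal(sum(comp_w$n), sum(bl$dominant != "missing"))
  comp_s <- composition(sites)
  expect_equal(sum(comp_s$n), sum(!is.na(sites$class)))
  # per-window counts add up to the classified sites of that window
  expect_equal(sum(bl$n_parent_a + bl$n_parent_b + bl$n_other),
               sum(!is.na(sites$class)))
})

test_that("100 kb windows agree with merged 50 kb counts when argmax is stable", {
  sites <- data.frame(
    chrom = "chr01",
    pos = c(1000, 2000, 60000, 70000, 80000, 110000, 160000, 170000),
    class = c("parent_a", "parent_a", "parent_a", "parent_b", "parent_a",
              "parent_b", "parent_b", "parent_b"),
    stringsAsFactors = FALSE
  )
  b50 <- window_paint(sites, c(chr01 = 200000), 50000)
  b100 <- window_paint(sites, c(chr01 = 200000), 100000)
  for (i in 1:2) {
    merged <- colSums(b50[(2 * i - 1):(2 * i),
                          c("n_parent_a", "n_parent_b", "n_other")])
    expect_equal(unlist(b100[i, c("n_parent_a", "n_parent_b", "n_other")]),
                 merged)
  }
  # both grids agree here because merging does not change the argmax
  expect_equal(b100$dominant, c("parent_a", "parent_b"))
})

test_that("painting recovers composition and window labels on a mosaic genome", {
  cfg <- sim_config(n_chrom = 4L, chrom_len = 400000L, seed = 71L,
                    scaffold_error_rate = 0)
  f <- simulate_founders(cfg)
  off <- simulate_offspring(f, cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_trio_vcf(f, off, cfg, vcf)
  sites <- classify_snps(filter_sites(vcf))
  lens <- stats::setNames(Biostrings::width(f$genomes$A), names(f$genomes$A))
  bl <- window_paint(sites, lens, 50000)
  label_of <- c(A = "parent_a", B = "parent_b", U = "other")
  mid <- (bl$start + pmin(bl$end, lens[bl$chrom])) / 2
  truth_lab <- label_of[vapply(seq_len(nrow(bl)), function(i)
    truth_origin_at(off$truth, bl$chrom[i], round(mid[i])), "")]
  informative <- bl$dominant != "missing"
  agree <- mean(bl$dominant[informative] == truth_lab[informative])
  expect_gte(agree, 0.95)
})

test_that("painting plot builds with the blue/red/green/white convention", {
  bl <- data.frame(chrom = "chr01", index = 1:4,
                   start = c(1, 50001, 100001, 150001),
                   end = c(50000, 100000, 150000, 200000),
                   n_parent_a = c(5, 0, 0, 0), n_parent_b = c(0, 5, 0, 0),
                   n_other = c(0, 0, 5, 0),
                   dominant = c("parent_a", "parent_b", "other", "missing"),
                   stringsAsFactors = FALSE)
  p <- plot_painting(bl)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_setequal(unique(built$data[[1]]$fill),
                  c("#2166ac", "#b2182b", "#1b7837", "#ffffff"))
})
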