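test_that("sim_config validates fractions, rates and lengths", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(target_fracs = c(0.5, 0.5, 0.5)), "summing to 1")
  expect_error(sim_config(snp_rate = 1.2), "snp_rate")
  expect_error(sim_config(chrom_len = 0), "chrom_len")
  expect_error(sim_config(min_segment_len = 2e5, mean_segment_len = 1e5),
               "min_segment_len")
})

test_that("founders are identical except at catalogued biallelic sites", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 20000L, snp_rate = 0.01,
                    seed = 5L)
  f <- simulate_founders(cfg)
  a <- as.character(f$genomes$A); b <- as.character(f$genomes$B)
  u <- as.character(f$genomes$U)
  for (chr in names(a)) {
    ca <- strsplit(a[[chr]], "")[[1]]
    cb <- strsplit(b[[chr]], "")[[1]]
    cu <- strsplit(u[[chr]], "")[[1]]
    diff_pos <- sort(unique(c(which(ca != cb), which(ca != cu),
                              which(cb != cu))))
    cat_pos <- sort(f$catalog$pos[f$catalog$chrom == chr])
    expect_true(all(diff_pos %in% cat_pos))
    # every catalogued site is biallelic and matches the recorded alleles
    rows <- f$catalog[f$catalog$chrom == chr, ]
    expect_equal(ca[rows$pos], rows$allele_a)
    expect_equal(cb[rows$pos], rows$allele_b)
    expect_equal(cu[rows$pos], rows$allele_u)
    n_alleles <- apply(cbind(rows$ref, rows$alt, rows$allele_a,
                             rows$allele_b, rows$allele_u), 1,
                       function(x) length(unique(x)))
    expect_true(all(n_alleles == 2L))
  }
})

test_that("snp_rate = 0 gives identical genomes and an empty catalog", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 5000L, snp_rate = 0, seed = 2L)
  f <- simulate_founders(cfg)
  expect_equal(nrow(f$catalog), 0L)
  expect_identical(as.character(f$genomes$A), as.character(f$genomes$B))
  expect_identical(as.character(f$genomes$A), as.character(f$genomes$U))
})

test_that("catalog size is within binomial bounds of L * snp_rate", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 100000L, snp_rate = 0.005,
                    seed = 9L)
  f <- simulate_founders(cfg)
  mean_n <- 1e5 * 0.005
  sd_n <- sqrt(1e5 * 0.005 * 0.995)
  expect_gt(nrow(f$catalog), mean_n - 3 * sd_n)
  expect_lt(nrow(f$catalog), mean_n + 3 * sd_n)
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 30000L, seed = 123L,
                    mean_segment_len = 10000, min_segment_len = 2000,
                    qual_low_frac = 0.1)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("degenerate fractions reproduce founder A with one segment", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 40000L,
                    target_fracs = c(1, 0, 0), seed = 4L,
                    mean_segment_len = 10000, min_segment_len = 1000)
  f <- simulate_founders(cfg)
  off <- simulate_offspring(f, cfg)
  expect_identical(as.character(off$genome), as.character(f$genomes$A))
  expect_equal(nrow(off$truth), 2L)  # one merged segment per chromosome
  expect_true(all(off$truth$origin == "A"))
})

test_that("truth segments tile each chromosome and fractions approach target", {
  cfg <- sim_config(n_chrom = 10L, chrom_len = 500000L,
                    mean_segment_len = 100000, min_segment_len = 0,
                    target_fracs = c(0.6, 0.25, 0.15), seed = 21L)
  f <- simulate_founders(sim_config(n_chrom = 10L, chrom_len = 500000L,
                                    snp_rate = 0.0005, seed = 21L))
  off <- simulate_offspring(f, cfg)
  for (chr in unique(off$truth$chrom)) {
    seg <- off$truth[off$truth$chrom == chr, ]
    expect_equal(seg$start[1], 1)
    expect_equal(seg$end[nrow(seg)], 500000)
    if (nrow(seg) > 1) {
      expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1))
      expect_true(all(seg$origin[-1] != seg$origin[-nrow(seg)]))
    }
  }
  fr <- truth_bp_fracs(off$truth)
  expect_lt(abs(fr[["A"]] - 0.6), 0.10)
})

test_that("scaffolds partition the genome and truth placements round-trip", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 60000L, scaffold_error_rate = 0,
                    scaffold_len_mean = 8000, scaffold_len_sd = 4000,
                    seed = 6L)
  f <- simulate_founders(cfg)
  scf <- fragment_to_scaffolds(f$genomes$A, cfg, revcomp_prob = 0)
  # forward, error-free: concatenation in truth order restores the genome
  for (chr in names(f$genomes$A)) {
    tr <- scf$truth[scf$truth$chrom == chr, ]
    tr <- tr[order(tr$start), ]
    rebuilt <- paste(as.character(scf$scaffolds[tr$scf_id]), collapse = "")
    expect_identical(rebuilt, as.character(f$genomes$A[[chr]]))
  }
  # conservation of bases
  expect_equal(sum(Biostrings::width(scf$scaffolds)),
               sum(Biostrings::width(f$genomes$A)))
  # with reverse-complementing, truth strand tells how to restore each piece
  scf2 <- fragment_to_scaffolds(f$genomes$A, cfg, revcomp_prob = 0.5)
  tr2 <- scf2$truth
  i <- which(tr2$strand == "-")[1]
  skip_if(is.na(i))
  piece <- as.character(Biostrings::reverseComplement(
    scf2$scaffolds[[tr2$scf_id[i]]]))
  expect_identical(piece, substr(as.character(f$genomes$A[[tr2$chrom[i]]]),
                                 tr2$start[i], tr2$end[i]))
})

test_that("empirical scaffold N50 is near the configured mean at 500 scaffolds", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 500L * 25000L,
                    snp_rate = 0, scaffold_len_mean = 25000,
                    scaffold_len_sd = 15000, scaffold_error_rate = 0,
                    seed = 31L)
  set.seed(31L)
  genome <- Biostrings::DNAStringSet(c(chr01 = paste(
    sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
    collapse = "")))
  scf <- fragment_to_scaffolds(genome, cfg, revcomp_prob = 0)
  expect_gt(length(scf$scaffolds), 300L)
  emp_n50 <- n50(Biostrings::width(scf$scaffolds))
  expect_gt(emp_n50, 25000 * 0.7)
  expect_lt(emp_n50, 25000 * 1.3)
})

test_that("trio VCF emits exactly the polymorphic sites with correct genotypes", {
  cfg <- sim_config(n_chrom = 2L, chrom_len = 50000L, snp_rate = 0.005,
                    seed = 8L)
  f <- simulate_founders(cfg)
  off <- simulate_offspring(f, cfg)
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  rec <- write_trio_vcf(f, off, cfg, vcf_path)
  # subset of catalog; every record polymorphic across the three samples
  expect_true(all(paste(rec$chrom, rec$pos) %in%
                  paste(f$catalog$chrom, f$catalog$pos)))
  expect_true(all(!(rec$off_allele == rec$allele_a &
                    rec$off_allele == rec$allele_b)))
  # a site where all three emitted samples agree never appears
  cat_key <- paste(f$catalog$chrom, f$catalog$pos)
  off_seq <- as.character(off$genome)
  off_all <- substring(off_seq[f$catalog$chrom], f$catalog$pos, f$catalog$pos)
  mono <- off_all == f$catalog$allele_a & off_all == f$catalog$allele_b
  expect_false(any(cat_key[mono] %in% paste(rec$chrom, rec$pos)))
  # offspring genotype equals the allele of its truth origin at each site
  sites <- filter_sites(vcf_path, min_qual = 0)
  expect_equal(nrow(sites), nrow(rec))
  for (i in sample.int(nrow(sites), 25L)) {
    org <- truth_origin_at(off$truth, sites$chrom[i], sites$pos[i])
    cat_row <- f$catalog[f$catalog$chrom == sites$chrom[i] &
                         f$catalog$pos == sites$pos[i], ]
    want <- switch(org, A = cat_row$allele_a, B = cat_row$allele_b,
                   U = cat_row$allele_u)
    expect_identical(sites$off[i], want)
  }
})

test_that("injected low-QUAL sites are exactly the ones a QUAL-30 filter removes", {
  cfg <- sim_config(n_chrom = 1L, chrom_len = 100000L, snp_rate = 0.005,
                    qual_low_frac = 0.1, seed = 14L)
  f <- simulate_founders(cfg)
  off <- simulate_offspring(f, cfg)
  vcf_path <- withr::local_tempfile(fileext = ".vcf")
  rec <- write_trio_vcf(f, off, cfg, vcf_path)
  kept <- filter_sites(vcf_path, min_qual = 30)
  expect_equal(nrow(kept), sum(rec$qual >= 30))
  expect_setequal(kept$pos, rec$pos[rec$qual >= 30])
})
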