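test_that("enzyme construction validates IUPAC codes and palindromy", {
  expect_error(restriction_enzyme("bad", "GXAT", 1), "IUPAC")
  expect_error(restriction_enzyme("bad", "GAAC", 1), "palindrome")
  expect_error(restriction_enzyme("bad", "GAATTC", 9), "cut_offset")
  apeki <- restriction_enzyme("ApeKI", "GCWGC", 1)
  expect_s3_class(apeki, "restriction_enzyme")
  defaults <- load_enzymes()
  expect_setequal(names(defaults), c("ApeKI", "PstI", "MspI", "EcoRI"))
  expect_equal(defaults$PstI$cut_offset, 5L)
})

test_that("find_sites locates exact and degenerate matches, with overlap", {
  toyE <- toy_enzyme()
  expect_equal(find_sites("TTGAATTCAA", toyE), 3L)
  gcwgc <- restriction_enzyme("deg", "GCWGC", 1)
  expect_equal(find_sites("TTGCAGCTT", gcwgc), 3L)
  expect_equal(find_sites("GCAGCAGC", gcwgc), c(1L, 4L))
  expect_equal(find_sites("TTTTTT", toyE), integer(0))
})

test_that("digestion of toy sequences yields the expected fragments", {
  toyE <- toy_enzyme()
  # zero sites: one fragment spanning the chromosome
  fr0 <- digest(c(chrA = "TTTTCCCC"), toyE)
  expect_equal(nrow(fr0), 1L)
  expect_equal(fr0$left_enzyme, "CHROM_END")
  expect_equal(fr0$right_enzyme, "CHROM_END")
  expect_equal(fr0$length, 8L)

  fr <- digest(c(chr1 = "TTGAATTCAA"), toyE)
  expect_equal(fr$start, c(0L, 3L))
  expect_equal(fr$end, c(3L, 10L))
  expect_equal(fr$left_enzyme, c("CHROM_END", "toyE"))
  expect_equal(fr$right_enzyme, c("toyE", "CHROM_END"))

  # overlapping degenerate sites: G | CAG | CAGC
  gcwgc <- restriction_enzyme("deg", "GCWGC", 1)
  g <- c(chr1 = "GCAGCAGC")
  fr2 <- digest(g, gcwgc)
  expect_equal(reconstruct_chromosome(as_genome(g), fr2, "chr1"), "GCAGCAGC")
  expect_equal(fr2$length, c(1L, 3L, 4L))
})

test_that("digestion agrees with the brute-force oracle on random sequences", {
  set.seed(42)
  enz <- gbs_enzymes()
  combos <- list(list(enz$ApeKI), list(enz$PstI, enz$MspI),
                 list(enz$ApeKI, enz$EcoRI))
  for (i in 1:40) {
    s <- random_dna(sample(50:2000, 1), gc = runif(1, 0.2, 0.6))
    for (es in combos) {
      frags <- digest(c(chr1 = s), es)
      expected <- oracle_fragments(s, es)
      got <- vapply(seq_len(nrow(frags)), function(j) {
        substr(s, frags$start[j] + 1L, frags$end[j])
      }, character(1))
      expect_identical(got, expected)
    }
  }
})

test_that("fragments partition each chromosome exactly", {
  set.seed(7)
  genome <- simulate_genome(40000, n_chromosomes = 3L, gc_content = 0.4)
  frags <- digest(genome, list(gbs_enzymes()$ApeKI, gbs_enzymes()$MspI))
  for (chrom in names(genome)) {
    fr <- frags[frags$chrom == chrom, ]
    fr <- fr[order(fr$start), ]
    expect_equal(sum(fr$length), length(genome[[chrom]]))
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])  # contiguous, ordered
    expect_equal(reconstruct_chromosome(genome, frags, chrom),
                 as.character(genome[[chrom]]))
  }
  # gc_fraction matches a direct count on a sample of fragments
  idx <- sample(nrow(frags), 20)
  for (j in idx) {
    s <- substr(as.character(genome[[frags$chrom[j]]]),
                frags$start[j] + 1L, frags$end[j])
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    expect_equal(frags$gc_fraction[j], gc)
  }
})

test_that("planted sites are recovered as exactly k internal cuts", {
  toyE <- toy_enzyme()
  genome <- simulate_genome(5000, gc_content = 0.5,
                            planted_sites = list(list(enzyme = toyE,
                                                      count = 8L)),
                            seed = 99)
  frags <- digest(genome, toyE)
  internal <- sum(frags$left_enzyme == "toyE")
  expect_equal(internal, 8L)
})

test_that("amplifiability rules follow the adapter chemistry", {
  enz <- gbs_enzymes()
  # single-enzyme protocol: chromosome-end fragments are excluded
  g <- c(chr1 = "TTTTGCAGCTTTTTGCTGCTTTT")
  fr <- digest(g, enz$ApeKI)
  amp <- select_amplifiable(fr, "single")
  expect_true(all(amp$left_enzyme == "ApeKI" & amp$right_enzyme == "ApeKI"))
  expect_equal(nrow(amp), nrow(fr) - 2L)

  # double digest with site order P, M, M, P: only P-M and M-P amplify
  s <- paste0("AAAA", "CTGCAG", "AAAA", "CCGG", "AAAA", "CCGG",
              "AAAA", "CTGCAG", "AAAA")
  fr2 <- digest(c(chr1 = s), list(enz$PstI, enz$MspI))
  expect_equal(nrow(fr2), 5L)
  amp2 <- select_amplifiable(fr2, "double_different_ends")
  expect_equal(nrow(amp2), 2L)
  expect_setequal(paste(amp2$left_enzyme, amp2$right_enzyme),
                  c("PstI MspI", "MspI PstI"))
  # a PstI-PstI fragment never amplifies under the double-digest rule
  expect_false(any(amp2$left_enzyme == amp2$right_enzyme))
  expect_error(select_amplifiable(fr2, "no_such_protocol"))
})

test_that("tags read inward from the cuts, reverse-complemented on the right", {
  set.seed(5)
  s <- random_dna(500)
  toyE <- toy_enzyme()
  s <- paste0(substr(s, 1, 100), "GAATTC", substr(s, 107, 300), "GAATTC",
              substr(s, 307, 500))
  g <- as_genome(c(chr1 = s))
  frags <- select_amplifiable(digest(g, toyE), "single")
  expect_equal(nrow(frags), 1L)
  tags <- extract_tags(g, frags, tag_length = 64L)
  expect_equal(nrow(tags), 2L)
  expect_equal(nchar(tags$sequence), c(64L, 64L))
  insert <- substr(s, frags$start + 1L, frags$end)
  expect_equal(tags$sequence[tags$side == "left"], substr(insert, 1, 64))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(insert, nchar(insert) - 63L, nchar(insert)))))
  expect_equal(tags$sequence[tags$side == "right"], rc)
})

test_that("short fragments truncate to insert length and deduplicate ends", {
  toyE <- toy_enzyme()
  s <- paste0("TT", "GAATTC", paste(rep("ACGT", 10), collapse = ""),
              "GAATTC", "TT")  # 46-base insert between the two cuts
  g <- as_genome(c(chr1 = s))
  frags <- select_amplifiable(digest(g, toyE), "single")
  expect_equal(frags$length, 46L)
  tags <- extract_tags(g, frags, tag_length = 64L)
  expect_equal(nrow(tags), 1L)  # right-end read is the exact reverse
  expect_equal(nchar(tags$sequence), 46L)
  expect_equal(tags$sequence, substr(s, frags$start + 1L, frags$end))
  expect_error(extract_tags(g, frags, tag_length = 0L), "tag_length")
})

test_that("spectra histogram fragments into the declared bins", {
  sb <- size_bins()
  expect_length(sb$labels, 15L)
  gb <- gc_bins()
  expect_length(gb$labels, 7L)

  fr <- data.frame(length = rep(150, 10), gc_fraction = rep(0, 10))
  sp <- spectrum(fr, sb)
  expect_equal(sp$frequency[2], 1)
  expect_equal(sum(sp$frequency), 1)
  spg <- spectrum(fr, gb)
  expect_equal(spg$frequency[1], 1)  # GC 0 falls in the lowest class

  # open-ended last bin takes out-of-range values
  fr2 <- data.frame(length = c(50, 2500), gc_fraction = c(0.1, 0.9))
  sp2 <- spectrum(fr2, sb)
  expect_equal(sp2$frequency[c(1, 15)], c(0.5, 0.5))

  # direct-counting equivalence on random lengths
  set.seed(1)
  lens <- sample(1:2000, 300, replace = TRUE)
  fr3 <- data.frame(length = lens, gc_fraction = runif(300))
  sp3 <- spectrum(fr3, sb)
  edges <- sb$edges
  manual <- vapply(seq_len(15), function(b) {
    sum(lens >= edges[b] & lens < edges[b + 1])
  }, numeric(1))
  expect_equal(sp3$count, manual)
})

test_that("observed equal to expected gives zero deviations that sum to zero", {
  set.seed(2)
  tags <- data.frame(fragment_length = sample(50:1500, 200, replace = TRUE),
                     fragment_gc = runif(200, 0.2, 0.6))
  ove <- observed_vs_expected(tags, rep(3, 200), size_bins())
  expect_equal(ove$deviation_pct, rep(0, 15))
  ove2 <- observed_vs_expected(tags, rpois(200, 40) + 1L, gc_bins())
  expect_equal(sum(ove2$deviation_pct), 0, tolerance = 1e-9)
})
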