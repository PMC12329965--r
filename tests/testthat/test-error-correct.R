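# error_correct: block finding, banded prefix edit distance, DFS correction

test_that("error blocks follow the frequency-threshold definition", {
  p <- tiny_params()
  set.seed(41)
  lin <- random_dna(3000)  # linear: no wraparound, unique syncmers
  tab <- build_syncmer_table(c(a = lin), p)
  params <- correction_params(theta = 3L)
  vec <- tab$vectors[tab$vectors$read == 1]
  stopifnot(!anyDuplicated(vec$index))

  # all frequencies >= theta: no blocks
  tab_hi <- tab; tab_hi$freq[] <- 99L
  expect_length(find_error_blocks(vec, tab_hi, params), 0L)

  # frequencies [9,9,1,2,9,...]: one block spanning rows 3-4, both boundaries
  tab_mid <- tab; tab_mid$freq[] <- 9L
  tab_mid$freq[vec$index[3:4]] <- c(1L, 2L)
  b <- find_error_blocks(vec, tab_mid, params)
  expect_length(b, 1L)
  expect_equal(b[[1]]$rows, 3:4)
  expect_equal(b[[1]]$left, 2L)
  expect_equal(b[[1]]$right, 5L)
  expect_false(b[[1]]$excluded)

  # all-error read is excluded
  tab_lo <- tab; tab_lo$freq[] <- 1L
  b2 <- find_error_blocks(vec, tab_lo, params)
  expect_length(b2, 1L)
  expect_true(b2[[1]]$excluded)
})

test_that("banded prefix edit distance matches direct semantics and full DP", {
  r <- prefix_edit_distance("ACGTACGT", "ACGTACGT", 5)
  expect_equal(c(r$d, r$g), c(0L, 0L))
  r <- prefix_edit_distance("ACGTACGT", "ACGT", 5)
  expect_equal(c(r$d, r$g), c(0L, 4L))
  r <- prefix_edit_distance("ACGTACGT", "TTTTTTTT", 2)
  expect_true(r$exceeded)

  # oracle: when the query consumes the whole target, d + g equals the full
  # O(nm) Levenshtein distance (utils::adist as the independent oracle)
  set.seed(17)
  for (i in 1:300) {
    n <- sample(20:200, 1)
    target <- random_dna(n)
    nmut <- sample(0:6, 1)
    query <- target
    for (m in seq_len(nmut)) {
      pos <- sample(nchar(query), 1)
      op <- sample(c("sub", "del", "ins"), 1)
      query <- switch(op,
        sub = paste0(substr(query, 1, pos - 1),
                     sample(c("A", "C", "G", "T"), 1),
                     substr(query, pos + 1, nchar(query))),
        del = paste0(substr(query, 1, pos - 1), substr(query, pos + 1, nchar(query))),
        ins = paste0(substr(query, 1, pos), sample(c("A", "C", "G", "T"), 1),
                     substr(query, pos + 1, nchar(query))))
    }
    r <- prefix_edit_distance(target, query, 15)
    expect_false(r$exceeded)
    expect_equal(r$d + r$g, as.integer(adist(target, query)))
  }
})

# At the unit-test k (31) error blocks are short, so the per-base budget is
# raised to keep eps*l >= 1 (the production default 0.01 is exercised at
# k = 301 in the acceptance suite).
unit_cparams <- function(...) correction_params(epsilon = 0.05, ...)

test_that("a mid-read substitution block is corrected to the truth vector", {
  p <- syncmer_params(k = 31L, s = 7L)
  set.seed(43)
  genome <- random_dna(2000)
  clean <- rep(genome, 30)
  names(clean) <- paste0("c", 1:30)
  # one read with a single substitution mid-read
  bad <- genome
  substr(bad, 1000, 1000) <- setdiff(c("A", "C", "G", "T"),
                                     substr(genome, 1000, 1000))[1]
  reads <- c(clean, err = bad)
  tab <- build_syncmer_table(reads, p)
  truth_vec <- tab$vectors[tab$vectors$read == 1]
  cr <- correct_reads(tab, unit_cparams())
  expect_gte(unname(cr$stats["corrected"]), 1)
  got <- cr$table$vectors[cr$table$vectors$read == 31]
  expect_equal(got$index, truth_vec$index)
  expect_equal(got$orient, truth_vec$orient)
  expect_equal(diff(got$pos), diff(truth_vec$pos))
  # fixed point: error-free input is untouched
  tabc <- build_syncmer_table(clean, p)
  cr2 <- correct_reads(tabc, unit_cparams())
  expect_equal(cr2$table$vectors, tabc$vectors)
  expect_equal(unname(cr2$stats["found"]), 0L)
})

test_that("two equally distant paths make correction ambiguous", {
  p <- syncmer_params(k = 31L, s = 7L)
  set.seed(44)
  left <- random_dna(300); right <- random_dna(300)
  # one variant site flanked by T; alleles A and C, the odd read carries G,
  # so both allele paths sit at hoco distance 1 from the block sequence
  mk <- function(b) paste0(left, "T", b, "T", right)
  reads <- c(setNames(rep(mk("A"), 10), paste0("a", 1:10)),
             setNames(rep(mk("C"), 10), paste0("b", 1:10)),
             odd = mk("G"))
  tab <- build_syncmer_table(reads, p)
  cr <- correct_reads(tab, unit_cparams())
  expect_gte(unname(cr$stats["ambiguous"]), 1L)
  expect_equal(unname(cr$stats["corrected"]), 0L)
  # with omega = 1 a tie still fails (e-hat < omega * e-tilde is strict)
  cr2 <- correct_reads(tab, correction_params(epsilon = 0.05, omega = 1))
  expect_gte(unname(cr2$stats["ambiguous"]), 1L)
})

test_that("the depth-search budget tau aborts dense searches", {
  p <- syncmer_params(k = 31L, s = 7L)
  set.seed(45)
  genome <- random_dna(1500)
  reads <- setNames(rep(genome, 10), paste0("r", 1:10))
  tab <- build_syncmer_table(reads, p)
  vec <- tab$vectors[tab$vectors$read == 1]
  tab$freq[vec$index[5]] <- 1L
  # the forged error entry occurs in all 10 identical reads: 10 blocks, and
  # tau = 0 forbids completing even one descent for each
  cr <- correct_reads(tab, unit_cparams(tau = 0L))
  expect_equal(unname(cr$stats["failed"]), 10L)
  expect_equal(unname(cr$stats["corrected"]), 0L)
})

test_that("correction accounting conserves and never invents syncmers", {
  fx <- circle_fixture(size = 6000, depth = 25, seed = 46,
                       sub_rate = 0.002, homo_rate = 0.01)
  p <- syncmer_params(k = 31L, s = 7L)
  tab <- build_syncmer_table(fx$reads, p)
  params <- correction_params()
  cr <- correct_reads(tab, params)
  st <- cr$stats
  expect_equal(unname(st["found"]),
               unname(st["corrected"] + st["ambiguous"] + st["failed"] + st["excluded"]))
  # corrected vectors only reference vertices of the trimmed graph or
  # original (uncorrected) occurrences
  trusted <- which(tab$freq >= params$theta)
  newly <- setdiff(unique(cr$table$vectors$index), unique(tab$vectors$index))
  expect_length(newly, 0L)
  added_occ <- cr$table$freq - tab$freq
  expect_true(all(which(added_occ > 0) %in% trusted))
})
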