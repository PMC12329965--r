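# assembly_graph: cleaning, unitig construction, read mapping, disentangling

test_that("cleaning is a fixed point on a clean high-coverage graph", {
  fx <- circle_fixture(size = 4000, depth = 20, seed = 51)
  tab <- build_syncmer_table(fx$reads, tiny_params())
  g <- build_kmer_graph(tab)
  g2 <- clean_graph(g, clean_params(cov_threshold = 5))
  expect_equal(g2$alive, g$alive)
  expect_equal(g2$edges, g$edges)
})

test_that("the coverage filter separates organelle from nuclear sequence", {
  set.seed(52)
  gen <- manual_genomes(list(circ = random_dna(5000), nuc = random_dna(20000)))
  gen$truth$circ$depth <- 60; gen$truth$nuc$depth <- 6
  gen$truth$nuc$circular <- FALSE
  reads <- simulate_reads(gen, readsim_config(seed = 53, sub_rate = 0, homo_rate = 0))
  tab <- build_syncmer_table(reads, tiny_params())
  g <- clean_graph(build_kmer_graph(tab), clean_params(cov_threshold = 30))
  ug <- build_unitig_graph(g)
  expect_equal(length(ug$name), 1L)
  expect_true(ug$circular[1])
  expect_true(syntig:::seq_rotation_equal(ug$seq[1], gen$records$seq[1]))
})

test_that("short dead-end branches are trimmed, long ones kept", {
  set.seed(54)
  core <- random_dna(6000)
  tipshort <- paste0(substr(core, 2995, 3000), random_dna(800))
  tiplong <- random_dna(2500)
  gen <- manual_genomes(list(circ = core))
  gen$truth$circ$depth <- 25
  reads <- simulate_reads(gen, readsim_config(seed = 55, sub_rate = 0, homo_rate = 0,
                                              min_len = 2000, mean_len = 3000, max_len = 4000))
  # branch reads: core prefix then divergent tail
  branch <- function(tail) paste0(substr(core, 2000, 3000), tail)
  tips <- data.frame(id = paste0("tip", 1:10),
                     seq = rep(branch(random_dna(800)), 10),
                     qual = NA, stringsAsFactors = FALSE)
  longb <- data.frame(id = paste0("long", 1:10),
                      seq = rep(branch(tiplong), 10),
                      qual = NA, stringsAsFactors = FALSE)
  p <- tiny_params()
  tab_short <- build_syncmer_table(rbind(reads, tips), p)
  g_short <- clean_graph(build_kmer_graph(tab_short),
                         clean_params(cov_threshold = 3, tip_len = 1000))
  ug_short <- build_unitig_graph(g_short)
  expect_equal(length(ug_short$name), 1L)  # tip removed, circle intact
  expect_true(ug_short$circular[1])

  tab_long <- build_syncmer_table(rbind(reads, longb), p)
  g_long <- clean_graph(build_kmer_graph(tab_long),
                        clean_params(cov_threshold = 3, tip_len = 1000))
  ug_long <- build_unitig_graph(g_long)
  expect_gt(length(ug_long$name), 1L)  # 2.5 kb branch survives
})

test_that("bubbles pop to the higher-coverage arm within the length bound", {
  set.seed(56)
  left <- random_dna(1200); right <- random_dna(1200)
  mid <- random_dna(150)
  mid2 <- mid
  substr(mid2, 75, 75) <- setdiff(c("A", "C", "G", "T"), substr(mid, 75, 75))[1]
  hap1 <- paste0(left, mid, right)
  hap2 <- paste0(left, mid2, right)
  reads <- c(setNames(rep(hap1, 20), paste0("a", 1:20)),
             setNames(rep(hap2, 6), paste0("b", 1:6)))
  p <- tiny_params()
  tab <- build_syncmer_table(reads, p)
  g <- clean_graph(build_kmer_graph(tab),
                   clean_params(cov_threshold = 3, tip_len = 10, bubble_len = 5000))
  ug <- build_unitig_graph(g)
  expect_equal(length(ug$name), 1L)  # bubble popped -> single chain
  expect_true(grepl(substr(mid, 60, 90), ug$seq[1], fixed = TRUE) ||
                grepl(rc(substr(mid, 60, 90)), ug$seq[1], fixed = TRUE))
})

test_that("unitig construction: chains, cycles, sequence reconstruction", {
  p <- tiny_params()
  set.seed(57)
  lin <- random_dna(1500)
  tab <- build_syncmer_table(setNames(rep(lin, 5), paste0("r", 1:5)), p)
  ug <- build_unitig_graph(build_kmer_graph(tab))
  expect_equal(length(ug$name), 1L)
  expect_equal(nrow(ug$edges), 0L)
  expect_false(ug$circular[1])
  # a chain unitig reproduces the read span between first and last syncmer
  v <- tab$vectors[tab$vectors$read == 1]
  h <- hoco_compress(lin)
  span <- hoco_expand(list(bases = substr(h$bases, v$pos[1] + 1, v$pos[nrow(v)] + p$k),
                           runs = h$runs[(v$pos[1] + 1):(v$pos[nrow(v)] + p$k)]))
  expect_true(ug$seq[1] == span || ug$seq[1] == rc(span))

  # isolated cycle -> single self-closing unitig, exact rotation of truth
  fx <- circle_fixture(size = 5000, depth = 15, seed = 58)
  tabc <- build_syncmer_table(fx$reads, p)
  ugc <- build_unitig_graph(build_kmer_graph(tabc))
  expect_equal(length(ugc$name), 1L)
  expect_true(ugc$circular[1])
  expect_equal(ugc$len[1], 5000L)
  expect_true(syntig:::seq_rotation_equal(ugc$seq[1], fx$truth))
})

test_that("reads map to unitig paths by seed-and-extend", {
  # quadripartite at small scale: repeat unitig with 2-in/2-out
  set.seed(59)
  p <- syncmer_params(k = 101L, s = 31L)
  lsc <- random_dna(4000); ir <- random_dna(1200); ssc <- random_dna(900)
  genome <- paste0(lsc, ir, ssc, rc(ir))
  gen <- manual_genomes(list(pl = genome), depth = 30)
  reads <- simulate_reads(gen, readsim_config(seed = 60, sub_rate = 0, homo_rate = 0,
                                              min_len = 1500, mean_len = 2500, max_len = 4000))
  asm <- syncmer_assemble(reads, p, correction = NULL, clean = clean_params(cov_threshold = 5),
                 min_component_bp = 1000L, disentangle_lambda = NULL)
  g <- asm$graph
  expect_equal(length(g$name), 3L)
  # a read wholly inside one unitig maps to a path of length 1
  paths <- asm$read_paths
  lens <- lengths(paths)
  expect_true(any(lens == 1L))
  # reads crossing the repeat name the specific in/out pair
  expect_true(any(lens >= 3L))
  # an unmappable read returns NULL
  vind <- syntig:::build_vertex_index(g)
  fake <- data.table::data.table(read = 1L, frag = 1L,
                                 index = rep(1L, 3), pos = c(0L, 50L, 100L),
                                 orient = c(0L, 0L, 0L))
  tabx <- build_syncmer_table(c(z = random_dna(600)), p)
  expect_null(map_read_to_unitigs(tabx$vectors, g, vind))
})

test_that("triplet domination resolves a figure-eight into two cycles", {
  # domination rule on x = [[100,1],[2,90]]: triplets (1,2),(2,1) dominated
  x <- matrix(c(100, 2, 1, 90), 2, 2)
  colmax <- apply(x, 2, max); rowmax <- apply(x, 1, max)
  dom <- x / rep(colmax, each = 2) < 0.1 & x / rowmax < 0.1
  expect_equal(which(dom), c(2L, 3L))  # (2,1) and (1,2)
  x2 <- matrix(50, 2, 2)
  dom2 <- x2 / rep(apply(x2, 2, max), each = 2) < 0.1 & x2 / apply(x2, 1, max) < 0.1
  expect_false(any(dom2))

  # end-to-end: two circles sharing one exact segment
  set.seed(61)
  shared <- random_dna(1500)
  ca <- paste0(random_dna(9000), shared)
  cb <- paste0(random_dna(13000), shared)
  gen <- manual_genomes(list(A = ca, B = cb), depth = 30)
  reads <- simulate_reads(gen, readsim_config(seed = 62, sub_rate = 0, homo_rate = 0,
                                              min_len = 4000, mean_len = 6000, max_len = 9000))
  p <- syncmer_params(k = 101L, s = 31L)
  asm <- syncmer_assemble(reads, p, correction = NULL, clean = clean_params(cov_threshold = 5),
                 min_component_bp = 1000L, disentangle_lambda = NULL)
  g0 <- asm$graph
  expect_equal(length(unique(g0$comp)), 1L)  # entangled
  g1 <- disentangle(g0)
  expect_equal(length(unique(g1$comp)), 2L)
  rp <- map_reads(g1)
  seqs <- vapply(sort(unique(g1$comp)), function(cid)
    resolve_component(g1, cid, rp)$seq, character(1))
  expect_true(any(vapply(seqs, syntig:::seq_rotation_equal, logical(1), b = ca)))
  expect_true(any(vapply(seqs, syntig:::seq_rotation_equal, logical(1), b = cb)))
})

test_that("disentangling preserves the k-mer content reachable by reads", {
  set.seed(63)
  shared <- random_dna(1200)
  ca <- paste0(random_dna(7000), shared)
  cb <- paste0(random_dna(11000), shared)
  gen <- manual_genomes(list(A = ca, B = cb), depth = 25)
  reads <- simulate_reads(gen, readsim_config(seed = 64, sub_rate = 0, homo_rate = 0,
                                              min_len = 4000, mean_len = 5000, max_len = 8000))
  p <- syncmer_params(k = 101L, s = 31L)
  asm <- syncmer_assemble(reads, p, correction = NULL, clean = clean_params(cov_threshold = 5),
                 min_component_bp = 1000L, disentangle_lambda = NULL)
  before <- sort(unique(abs(unlist(asm$graph$vpath))))
  g1 <- disentangle(asm$graph)
  after <- sort(unique(abs(unlist(g1$vpath))))
  expect_equal(after, before)
})

test_that("debris components below 10 kb are dropped", {
  set.seed(65)
  gen <- manual_genomes(list(big = random_dna(15000), small = random_dna(3000)),
                        depth = 20)
  reads <- simulate_reads(gen, readsim_config(seed = 66, sub_rate = 0, homo_rate = 0))
  asm <- syncmer_assemble(reads, tiny_params(), correction = NULL,
                 clean = clean_params(cov_threshold = 3))
  expect_equal(length(asm$graph$name), 1L)
  expect_equal(asm$graph$len[1], 15000L)
})
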