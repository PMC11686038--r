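make_em <- function(counts, systems, stages, reps) {
  samples <- data.frame(sample = colnames(counts), system = systems,
                        stage = stages, replicate = reps,
                        stringsAsFactors = FALSE)
  expression_matrix(counts, samples)
}

test_that("median-of-ratios size factors recover scaling and depth", {
  cnt <- matrix(rpois(200, 50), ncol = 2,
                dimnames = list(sprintf("g%03d", 1:100), c("s1", "s2")))
  em <- make_em(cnt, c("A", "A"), c("D0", "D0"), 1:2)
  expect_equal(unname(normalize_counts(make_em(cbind(s1 = cnt[, 1], s2 = cnt[, 1]),
                                               c("A", "A"), c("D0", "D0"), 1:2))$size_factors),
               c(1, 1))
  doubled <- cbind(s1 = cnt[, 1], s2 = 2L * cnt[, 1])
  sf <- normalize_counts(make_em(doubled, c("A", "A"), c("D0", "D0"), 1:2))$size_factors
  expect_equal(unname(sf[2] / sf[1]), 2)

  zero <- cnt; zero[, 2] <- 0L
  expect_error(normalize_counts(make_em(zero, c("A", "A"), c("D0", "D0"), 1:2)),
               "all-zero")

  # NB simulation: recover planted depth factors within 5%
  set.seed(31)
  depth <- c(0.6, 0.9, 1.0, 1.4, 2.0)
  mu <- rlnorm(2000, log(100), 1)
  cnt2 <- sapply(depth, function(d) rnbinom(2000, mu = mu * d, size = 20))
  dimnames(cnt2) <- list(paste0("g", 1:2000), paste0("s", 1:5))
  em2 <- normalize_counts(make_em(cnt2, rep("A", 5), rep("D0", 5), 1:5))
  rel <- em2$size_factors / em2$size_factors[3]
  expect_true(all(abs(rel / (depth / depth[3]) - 1) < 0.05))
})

test_that("size factors agree with the established median-of-ratios implementation", {
  set.seed(32)
  cnt <- sapply(c(0.5, 1, 1.5, 2), function(d)
    rnbinom(500, mu = rlnorm(500, log(80), 1) * d, size = 10))
  dimnames(cnt) <- list(paste0("g", 1:500), paste0("s", 1:4))
  em <- normalize_counts(make_em(cnt, rep("A", 4), rep("D0", 4), 1:4))
  ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
  expect_equal(unname(em$size_factors), unname(ref), tolerance = 1e-8)
})

sim_two_group <- function(n_genes, n_planted, lfc, dispersion, reps = 3,
                          mu0 = 100) {
  mu <- rlnorm(n_genes, log(mu0), 0.4)
  planted <- seq_len(n_planted)
  mu_trt <- mu
  mu_trt[planted] <- mu[planted] * 2^lfc
  cnt <- cbind(
    sapply(seq_len(reps), function(i) rnbinom(n_genes, mu = mu_trt, size = 1 / dispersion)),
    sapply(seq_len(reps), function(i) rnbinom(n_genes, mu = mu, size = 1 / dispersion)))
  dimnames(cnt) <- list(sprintf("g%05d", seq_len(n_genes)),
                        paste0("s", seq_len(2 * reps)))
  em <- make_em(cnt, rep(c("T", "C"), each = reps), rep("D0", 2 * reps),
                rep(seq_len(reps), 2))
  list(em = normalize_counts(em), planted = rownames(cnt)[planted])
}

test_that("call_de detects planted effects and reports ns for equal means", {
  set.seed(41)
  sim <- sim_two_group(1500, 200, lfc = 2, dispersion = 0.05)
  de <- call_de(sim$em, "T", "D0", "C")
  expect_named(de, c("gene", "system", "stage", "log2FC", "padj", "direction"))
  hit <- de$direction[match(sim$planted, de$gene)] == "up"
  expect_gte(mean(hit), 0.95)  # power on 200 planted 4-fold genes

  # a gene with identical group means is ns
  flat <- matrix(rep(c(100L, 100L, 100L), 2), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  flat <- rbind(flat, matrix(rpois(6 * 50, 80), ncol = 6,
                             dimnames = list(paste0("n", 1:50), paste0("s", 1:6))))
  emf <- normalize_counts(make_em(flat, rep(c("T", "C"), each = 3),
                                  rep("D0", 6), rep(1:3, 2)))
  def <- call_de(emf, "T", "D0", "C", min_mean = 1)
  expect_equal(def$direction[def$gene == "g1"], "ns")
  # size factors from the random null genes shift the means marginally
  expect_lt(abs(def$log2FC[def$gene == "g1"]), 0.05)

  expect_error(call_de(sim$em, "nope", "D0", "C"), "unknown group")
})

test_that("the plain Welch method calls strong low-dispersion effects", {
  set.seed(43)
  sim <- sim_two_group(800, 100, lfc = 2, dispersion = 0.005)
  de <- call_de(sim$em, "T", "D0", "C", method = "welch")
  hit <- de$direction[match(sim$planted, de$gene)] == "up"
  expect_gte(mean(hit), 0.9)
  null_called <- de$direction[!de$gene %in% sim$planted] != "ns"
  expect_lte(mean(null_called), 0.05)
})

test_that("single-replicate groups fall back to fold-change-only calls", {
  cnt <- matrix(c(400L, 100L, 90L, 110L), nrow = 2,
                dimnames = list(c("g1", "g2"), c("t1", "c1")))
  cnt <- rbind(cnt, matrix(rpois(2 * 30, 100), ncol = 2,
                           dimnames = list(paste0("n", 1:30), c("t1", "c1"))))
  em <- normalize_counts(make_em(cnt, c("T", "C"), c("D0", "D0"), c(1, 1)))
  de <- call_de(em, "T", "D0", "C")
  expect_equal(de$direction[de$gene == "g1"], "up")
  expect_equal(de$direction[de$gene == "g2"], "ns")
})

test_that("read_external_de validates columns and handles NA padj", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "de.tsv")
  writeLines(c("gene\tlog2FC\tpadj", "g1\t2.5\t0.001", "g2\t-1.4\tNA",
               "g3\t0.2\t0.9"), f)
  de <- read_external_de(f, system = "S4", stage = "D4")
  expect_equal(nrow(de), 3L)
  expect_equal(de$direction, c("up", "ns", "ns"))

  writeLines(c("gene\tlog2FoldChange\tpadj", "g1\t-3\t0.0001"), f)
  expect_equal(read_external_de(f)$direction, "down")

  writeLines(c("gene\tlog2FC\tpadj", "g1\t1\t0.1", "g1\t2\t0.01"), f)
  expect_error(read_external_de(f), "duplicate")
  writeLines(c("gene\tlfc\tpadj", "g1\t1\t0.1"), f)
  expect_error(read_external_de(f), "columns")
})

test_that("integration applies the both-direction exclusion rule", {
  de <- data.frame(
    gene = c("gA", "gA", "gB", "gC", "gC", "gD"),
    system = "S4",
    stage = c("D4", "D10", "D4", "D0", "D7", "D10"),
    log2FC = c(2, -2, 1.5, 1.2, 1.8, 0.1),
    padj = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.8),
    direction = c("up", "down", "up", "up", "up", "ns"))
  sets <- integrate_system_de(de, "S4")
  expect_equal(sets$excluded, "gA")      # up at D4, down at D10
  expect_setequal(sets$up, c("gB", "gC"))
  expect_length(sets$down, 0L)
  expect_false("gD" %in% c(sets$up, sets$down, sets$excluded))
  expect_length(intersect(sets$up, sets$down), 0L)
})

test_that("cross-system combinations follow the exhaustive direction oracle", {
  states <- c("up", "down", "ns")
  grid <- expand.grid(S4 = states, O4 = states, `O+S` = states,
                      stringsAsFactors = FALSE)
  names(grid)[3] <- "O+S"
  for (i in seq_len(nrow(grid))) {
    st <- unlist(grid[i, ])
    sets <- lapply(st, function(d) {
      structure(list(system = "x",
                     up = if (d == "up") "g1" else character(0),
                     down = if (d == "down") "g1" else character(0),
                     excluded = character(0)),
                class = "SystemDirectionSets")
    })
    res <- classify_cross_system(sets, "up")
    has_up <- any(st == "up")
    has_down <- any(st == "down")
    if (has_up && !has_down) {
      expect_equal(res$combination,
                   paste(names(st)[st == "up"], collapse = "/"),
                   info = paste(st, collapse = ","))
    } else {
      expect_equal(nrow(res), 0L, info = paste(st, collapse = ","))
    }
  }
})

test_that("endpoint ratio bins include their boundaries", {
  expect_equal(as.character(bin_by_endpoint_ratio(19, 9)), "high")  # ratio 2.0
  expect_equal(as.character(bin_by_endpoint_ratio(9, 19)), "low")   # ratio 0.5
  expect_equal(as.character(bin_by_endpoint_ratio(100, 100)), "mid")
  expect_equal(as.character(bin_by_endpoint_ratio(c(399, 0), c(99, 1000))),
               c("high", "low"))
  expect_error(bin_by_endpoint_ratio(-1, 5), ">= 0")
})

test_that("cluster labels follow the fixed combination x bin order", {
  bins <- setNames(factor(c("high", "mid", "low"), levels = c("high", "mid", "low")),
                   c("g1", "g2", "g3"))
  combos <- data.frame(gene = c("g1", "g2", "g3"),
                       combination = c("S4/O4/O+S", "S4", "O4"))
  up <- assemble_clusters(combos, bins, "up")
  expect_equal(up$label, c("UC1", "UC17", "UC21"))
  down <- assemble_clusters(combos, bins, "down")
  expect_equal(down$label, c("DC1", "DC17", "DC21"))

  single <- assemble_clusters(data.frame(gene = c("g1", "g3"), combination = "S4"),
                              bins, "up", mode = "single_system")
  expect_equal(single$label, c("C1", "C3"))
  single_dn <- assemble_clusters(data.frame(gene = "g2", combination = "S4"),
                                 bins, "down", mode = "single_system")
  expect_equal(single_dn$label, "C5")

  expect_error(assemble_clusters(data.frame(gene = "g1", combination = "huh"),
                                 bins, "up"), "unknown combination")

  # partition: every classified gene appears exactly once per direction
  set.seed(51)
  genes <- sprintf("r%03d", 1:100)
  combos2 <- data.frame(gene = genes,
                        combination = sample(c("S4", "O4", "O+S", "S4/O4"),
                                             100, replace = TRUE))
  bins2 <- setNames(sample(c("high", "mid", "low"), 100, replace = TRUE), genes)
  cl <- assemble_clusters(combos2, bins2, "up")
  expect_equal(sort(cl$gene), sort(genes))
  expect_true(all(table(cl$gene) == 1L))
  expect_lte(length(unique(cl$label)), 21L)
})

test_that("within-cluster ranking groups genes by peak stage then gene id", {
  stages <- c("D0", "D4", "D7", "D10")
  prof0 <- rbind(                      # one column per stage
    gLate = c(10, 10, 10, 100),
    gEarly = c(100, 10, 10, 10),
    aTie = c(50, 10, 50, 10),
    bTie = c(50, 10, 50, 10))
  cnt <- prof0[, rep(1:4, each = 2)]   # two replicates per stage
  colnames(cnt) <- paste0("s", 1:8)
  em <- make_em(cnt, rep("S4", 8), rep(stages, each = 2), rep(1:2, 4))
  em$normalized <- TRUE
  rk <- rank_within_cluster(c("gLate", "gEarly", "bTie", "aTie"), em, "S4",
                            direction = "up", stages = stages)
  expect_equal(rk$gene, c("aTie", "bTie", "gEarly", "gLate"))
  expect_equal(rk$peak_stage, c("D0", "D0", "D0", "D10"))

  # down direction uses the minimum
  rk_dn <- rank_within_cluster(c("gLate", "gEarly"), em, "S4",
                               direction = "down", stages = stages)
  expect_equal(rk_dn$peak_stage[rk_dn$gene == "gEarly"], "D4")

  # 20-gene fixture against a hand-written sort
  set.seed(53)
  genes <- sprintf("h%02d", 1:20)
  prof <- matrix(runif(20 * 4, 10, 100), nrow = 20, dimnames = list(genes, NULL))
  cnt2 <- prof[, rep(1:4, each = 2)]
  colnames(cnt2) <- paste0("t", 1:8)
  em2 <- make_em(cnt2, rep("S4", 8), rep(stages, each = 2), rep(1:2, 4))
  em2$normalized <- TRUE
  rk2 <- rank_within_cluster(genes, em2, "S4", "up", stages = stages)
  manual <- genes[order(apply(prof, 1, which.max), genes)]
  expect_equal(rk2$gene, manual)
})
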