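test_that("classify_trajectory matches its definition on canonical cases", {
  expect_equal(classify_trajectory(c(0, 1, 1, 1, 1, 1)), "CO1")
  expect_equal(classify_trajectory(c(1, 1, 1, 1, 1, 1)), "PO")
  expect_equal(classify_trajectory(c(0, 0, 0, 0, 0, 1)), "CO5")
  expect_equal(classify_trajectory(c(0, 1, 0, 1, 1, 1)), "CO3")
  expect_equal(classify_trajectory(c(1, 0, 0, 0, 0, 0)), "OC1")
  expect_equal(classify_trajectory(c(1, 1, 1, 1, 1, 0)), "OC5")
  expect_equal(classify_trajectory(c(0, 0, 1, 0, 0, 0)), "TRANSIENT")
  expect_equal(classify_trajectory(c(0, 0, 0, 0, 0, 0)), "NEVER_OPEN")
  expect_equal(classify_trajectory(c(1, 0, 1, 1, 1, 1)), "PO_UNSTABLE")
  expect_error(classify_trajectory(c(0, 1)), "3 stages")
  expect_error(classify_trajectory(c(0, 1, NA, 1, 1, 1)), "complete")
})

test_that("open/close bit-flip duality exchanges CO_k and OC_k over all 64 patterns", {
  pats <- all_patterns()
  cls <- classify_patterns(pats)
  flipped <- classify_patterns(!pats)
  swap <- function(x) {
    y <- x
    y[grepl("^CO", x)] <- sub("CO", "OC", x[grepl("^CO", x)])
    y[grepl("^OC", x)] <- sub("OC", "CO", x[grepl("^OC", x)])
    y[x == "PO"] <- "NEVER_OPEN"
    y[x == "NEVER_OPEN"] <- "PO"
    y[x == "PO_UNSTABLE"] <- "TRANSIENT"
    y[x == "TRANSIENT"] <- "PO_UNSTABLE"
    y
  }
  expect_identical(flipped, swap(cls))
})

test_that("strict-monotone mode reclassifies only non-monotone transitions", {
  expect_equal(classify_trajectory(c(0, 1, 0, 1, 1, 1), mode = "strict_monotone"),
               "TRANSIENT")
  expect_equal(classify_trajectory(c(0, 0, 1, 1, 1, 1), mode = "strict_monotone"),
               "CO2")
  expect_equal(classify_trajectory(c(1, 1, 0, 1, 0, 0), mode = "strict_monotone"),
               "TRANSIENT")
  expect_equal(classify_trajectory(c(1, 1, 0, 0, 0, 0), mode = "strict_monotone"),
               "OC2")
  # monotone patterns agree between modes
  pats <- all_patterns()
  strict <- classify_patterns(pats, mode = "strict_monotone")
  default <- classify_patterns(pats)
  mono <- apply(pats, 1L, function(b) sum(abs(diff(b))) <= 1L)
  expect_identical(strict[mono], default[mono])
})

test_that("build_background merges all samples and rejects empty input", {
  a <- gr_of("chr1", c(100, 1000), c(200, 1100))
  b <- gr_of("chr2", 500, 700)
  bg <- build_background(list(a, b))
  expect_length(bg, 3L)
  expect_identical(build_background(list(a, a)), merge_intervals(a))
  expect_error(build_background(list(gr_of("chr1", 1, 2)[0])), "empty")

  set.seed(3)
  sets <- replicate(8, random_peaks(150), simplify = FALSE)
  bg <- build_background(sets)
  expect_equal(sum(width(bg)), bf_union_bases(sets))
})

test_that("compute_occupancy calls a region open exactly when a sample peak overlaps it", {
  bg <- gr_of("chr1", c(1000, 5000, 9000), c(1400, 5400, 9400))
  mk <- function(open_at) {
    st <- lapply(DEFAULT_STAGES, function(t) {
      if (t %in% open_at) gr_of("chr1", 5000, 5400) else gr_of("chr1", 1, 2)[0]
    })
    names(st) <- DEFAULT_STAGES
    st
  }
  occ <- compute_occupancy(bg, list(X = mk("D4"), Y = mk(character(0))))
  expect_true(occ$open$X[2, "D4"])
  expect_false(any(occ$open$X[2, setdiff(DEFAULT_STAGES, "D4")]))
  expect_false(any(occ$open$Y))  # possible under a shared background
  # error names every missing (system, stage) pair
  expect_error(compute_occupancy(bg, list(X = mk("D4")[1:3])), "X:D7.*X:ESC")
})

test_that("classify_system counts cross-foot and are order-invariant", {
  set.seed(5)
  bg <- merge_intervals(random_peaks(300, chroms = "chrA"))
  n <- length(bg)
  sys <- list(A = lapply(setNames(nm = DEFAULT_STAGES), function(t) {
    bg[sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.6, 0.4))]
  }))
  occ <- compute_occupancy(bg, sys)
  asg <- classify_system(occ, "A")
  expect_equal(sum(asg$counts), n)

  # all-open fixture: everything PO
  sys_all <- list(B = lapply(setNames(nm = DEFAULT_STAGES), function(t) bg))
  asg_all <- classify_system(compute_occupancy(bg, sys_all), "B")
  expect_equal(unname(asg_all$counts[["PO"]]), n)
  expect_equal(sum(asg_all$counts) - asg_all$counts[["PO"]], 0L)

  # permuting occupancy rows leaves counts unchanged
  perm <- sample.int(n)
  occ2 <- occ
  occ2$regions <- occ2$regions[perm]
  occ2$open$A <- occ2$open$A[perm, ]
  expect_equal(as.vector(classify_system(occ2, "A")$counts),
               as.vector(asg$counts))
})

test_that("compare_systems satisfies its set identities", {
  set.seed(9)
  bg <- merge_intervals(random_peaks(200, chroms = "chrA"))
  n <- length(bg)
  rand_assign <- function(sys) {
    lv <- trajectory_classes()
    cls <- factor(sample(lv, n, replace = TRUE), levels = lv)
    structure(list(system = sys, regions = bg, stages = DEFAULT_STAGES,
                   class = cls, counts = table(cls)),
              class = "CADsAssignment")
  }
  a <- rand_assign("A")
  b <- rand_assign("B")
  scope <- c(paste0("CO", 1:4))
  cmp <- compare_systems(a, b, scope)
  in_a <- which(a$class %in% scope)
  expect_setequal(c(cmp$common, cmp$specific_a), in_a)
  expect_length(intersect(cmp$common, cmp$specific_a), 0L)
  expect_length(intersect(cmp$common, cmp$specific_b), 0L)

  same <- compare_systems(a, a, scope)
  expect_length(same$specific_a, 0L)
  expect_length(same$specific_b, 0L)

  short <- rand_assign("C")
  short$regions <- bg[-1]
  short$class <- short$class[-1]
  expect_error(compare_systems(a, short, scope), "background")
})

test_that("synergy_patterns partitions the combined system's transitions", {
  set.seed(13)
  bg <- merge_intervals(random_peaks(200, chroms = "chrA"))
  n <- length(bg)
  lv <- trajectory_classes()
  mk <- function(sys, cls) {
    cls <- factor(cls, levels = lv)
    structure(list(system = sys, regions = bg, stages = DEFAULT_STAGES,
                   class = cls, counts = table(cls)),
              class = "CADsAssignment")
  }
  for (trial in 1:20) {
    os <- mk("O+S", sample(lv, n, replace = TRUE))
    s4 <- mk("S4", sample(lv, n, replace = TRUE))
    o4 <- mk("O4", sample(lv, n, replace = TRUE))
    syn <- synergy_patterns(os, s4, o4)
    co_os <- which(os$class %in% paste0("CO", 1:4))
    parts <- syn$open
    expect_setequal(unlist(parts), co_os)
    expect_equal(sum(lengths(parts)), length(co_os))  # pairwise disjoint
    oc_os <- which(os$class %in% paste0("OC", 1:4))
    expect_setequal(unlist(syn$close), oc_os)
    expect_equal(sum(lengths(syn$close)), length(oc_os))
  }
  # identical CO sets in all three systems: everything is the all-three set
  cls <- sample(lv, n, replace = TRUE)
  syn_same <- synergy_patterns(mk("O+S", cls), mk("S4", cls), mk("O4", cls))
  expect_length(syn_same$open$with_s4, 0L)
  expect_length(syn_same$open$os_only, 0L)
  expect_equal(length(syn_same$open$all_three),
               sum(cls %in% paste0("CO", 1:4)))
  # empty single-factor CO sets: everything is O+S-only
  none <- rep("NEVER_OPEN", n)
  syn_only <- synergy_patterns(mk("O+S", cls), mk("S4", none), mk("O4", none))
  expect_equal(length(syn_only$open$os_only), sum(cls %in% paste0("CO", 1:4)))
})

test_that("subtract_control excludes whole peaks by overlap", {
  sys <- gr_of("chr1", c(100, 500, 900), c(200, 600, 1000))
  expect_identical(subtract_control(sys, sys[0]), sys)
  expect_length(subtract_control(sys, gr_of("chr1", 0, 2000)), 0L)

  set.seed(21)
  x <- random_peaks(150)
  y <- random_peaks(80)
  expect_identical(subtract_control(x, y), x[!bf_overlaps(x, y)])
})
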