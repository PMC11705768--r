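# Reading, validation, and construction of the evidence matrices.

test_that("expression panel round-trips through TSV losslessly", {
  panel <- tiny_panel()
  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_expression_panel(panel, f, fm)
  back <- read_expression_panel(f, fm)
  expect_identical(back$values, panel$values)
  expect_identical(back$sample_tissue, panel$sample_tissue)

  # synthetic fixture written then reread
  sim <- simulate_dataset(simulation_spec(n_genes = 5, n_tissues = 3,
                                          samples_per_tissue = 30,
                                          slides_per_gene = 6, seed = 2))
  write_expression_panel(sim$Y, f, fm)
  expect_equal(read_expression_panel(f, fm)$values, sim$Y$values)
})

test_that("expression panel input validation", {
  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "gA\t1\t-1"), f)
  writeLines(c("sample\ttissue", "s1\tliver", "s2\tliver"), fm)
  expect_error(read_expression_panel(f, fm), "negative")

  writeLines(c("id\ts1\ts2", "gA\t1\t2"), f)
  writeLines(c("sample\ttissue", "s1\tliver"), fm)
  expect_error(read_expression_panel(f, fm), "s2")
})

test_that("all-missing gene rows are dropped with a message", {
  f <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "gA\t1\t2", "gB\tNA\tNA"), f)
  writeLines(c("sample\ttissue", "s1\tliver", "s2\tliver"), fm)
  expect_message(panel <- read_expression_panel(f, fm), "1 gene")
  expect_identical(rownames(panel$values), "gA")
})

test_that("detection fractions count strictly above the cutoff", {
  panel <- tiny_panel()
  dist <- build_tissue_distribution(panel, cutoff = 0, min_samples = 3)
  # gA liver values (0,1,5): 2/3 detected at cutoff 0
  expect_equal(dist$fractions["gA", "liver"], 2 / 3)
  # gB lung values (0,0,9): 1/3
  expect_equal(dist$fractions["gB", "lung"], 1 / 3)
  # all values <= cutoff -> fraction 0 everywhere
  high <- build_tissue_distribution(panel, cutoff = 10, min_samples = 3)
  expect_true(all(high$fractions == 0))
})

test_that("detection fractions match a brute-force counting oracle", {
  panel <- random_panel()
  cutoff <- 1.5
  dist <- build_tissue_distribution(panel, cutoff, min_samples = 2)
  for (g in rownames(panel$values)) {
    for (t in colnames(dist$fractions)) {
      idx <- names(panel$sample_tissue)[panel$sample_tissue == t]
      manual <- sum(panel$values[g, idx] > cutoff) / length(idx)
      expect_equal(dist$fractions[g, t], manual)
    }
  }
})

test_that("fractions lie in [0,1] and are monotone non-increasing in cutoff", {
  panel <- random_panel(seed = 13)
  cuts <- c(0, 0.5, 1, 2, 4, 8)
  prev <- NULL
  for (cutoff in cuts) {
    d <- build_tissue_distribution(panel, cutoff, min_samples = 2)$fractions
    expect_true(all(d >= 0 & d <= 1))
    if (!is.null(prev)) expect_true(all(d <= prev))
    prev <- d
  }
})

test_that("min_samples filters tissues and can empty the panel", {
  panel <- tiny_panel()
  expect_error(build_tissue_distribution(panel, 0, min_samples = 10),
               "min_samples")
  d <- build_tissue_distribution(panel, 0, min_samples = 3)
  expect_setequal(colnames(d$fractions), c("liver", "lung"))
})

test_that("optimize_detection_cutoff recovers a planted cutoff", {
  panel <- random_panel(n_genes = 40, seed = 17)
  c_star <- 2
  truth <- build_tissue_distribution(panel, c_star, min_samples = 2)
  ref <- (truth$fractions > 0) * 1L
  res <- optimize_detection_cutoff(panel, ref,
                                   candidate_cutoffs = c(0, c_star,
                                                         10 * c_star),
                                   min_samples = 2)
  expect_equal(res$cutoff, c_star)
  expect_equal(nrow(res$table), 3L)

  # single candidate comes straight back with its scores
  one <- optimize_detection_cutoff(panel, ref, candidate_cutoffs = 1,
                                   min_samples = 2)
  expect_equal(one$cutoff, 1)
  expect_true(all(c("spearman", "aupr") %in% names(one$table)))
})

test_that("cutoff criterion ties break toward the smallest cutoff", {
  # a cutoff between consecutive observed values changes nothing, so two
  # candidates in the same gap tie exactly
  panel <- random_panel(n_genes = 30, seed = 19)
  ref <- (build_tissue_distribution(panel, 2, 2)$fractions > 0.5) * 1L
  res <- optimize_detection_cutoff(panel, ref,
                                   candidate_cutoffs = c(1e-9, 2e-9),
                                   min_samples = 2)
  expect_equal(res$cutoff, 1e-9)
  expect_equal(res$table$spearman[1], res$table$spearman[2])
})

test_that("constant reference is rejected", {
  panel <- tiny_panel()
  ref <- matrix(1, 2, 2, dimnames = list(c("gA", "gB"),
                                         c("liver", "lung")))
  expect_error(optimize_detection_cutoff(panel, ref, 0, min_samples = 2),
               "constant")
})

test_that("protein annotation parsing rescales and expands labels", {
  # no rescale needed: counts (2,1,0,1) at P = 4 -> codes (0,0,1,3)
  path <- write_hpa_table(list(gA = c(2, 1, 0, 1)))
  panel <- parse_protein_annotations(path, target_slide_count = 4)
  expect_identical(unname(panel$labels["gA", ]), c(0L, 0L, 1L, 3L))

  # exact doubling to P = 8
  panel8 <- parse_protein_annotations(path, target_slide_count = 8)
  expect_identical(as.integer(table(factor(panel8$labels["gA", ], 0:3))),
                   c(4L, 2L, 0L, 2L))
})

test_that("auto slide count matches a largest-remainder oracle", {
  set.seed(31)
  counts <- lapply(1:20, function(i) rmultinom(1, sample(4:40, 1),
                                               c(.3, .2, .2, .3))[, 1])
  names(counts) <- sprintf("g%02d", 1:20)
  path <- write_hpa_table(counts)
  panel <- parse_protein_annotations(path, "auto")
  P <- as.integer(round(mean(vapply(counts, sum, 0))))
  expect_equal(ncol(panel$labels), P)

  # independent largest-remainder oracle per gene
  oracle <- function(cnt, total) {
    share <- cnt * total / sum(cnt)
    out <- floor(share)
    left <- total - sum(out)
    ord <- order(share - out, decreasing = TRUE)
    k <- 1
    while (left > 0) {
      out[ord[k]] <- out[ord[k]] + 1
      left <- left - 1; k <- k + 1
    }
    out
  }
  for (g in rownames(panel$labels)) {
    got <- as.integer(table(factor(panel$labels[g, ], 0:3)))
    expect_identical(got, as.integer(oracle(counts[[g]], P)))
    expect_equal(sum(got), P)
  }
})

test_that("label proportion rank order is conserved by rescaling", {
  set.seed(33)
  counts <- lapply(1:10, function(i) sample(0:15, 4, replace = TRUE) + 1L)
  names(counts) <- sprintf("g%02d", 1:10)
  panel <- parse_protein_annotations(write_hpa_table(counts), 50)
  for (g in names(counts)) {
    got <- as.integer(table(factor(panel$labels[g, ], 0:3)))
    # strict input orderings may not invert (ties can arise from rounding)
    for (i in 1:3) for (j in (i + 1):4) {
      if (counts[[g]][i] > counts[[g]][j]) {
        expect_gte(got[i], got[j])
      }
    }
  }
})

test_that("protein parser error paths", {
  path <- write_hpa_table(list(gA = c(1, 1, 1, 1)))
  tab <- read.delim(path, check.names = FALSE)
  tab$Level[2] <- "Mediumish"
  bad <- tempfile(fileext = ".tsv")
  write.table(tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_protein_annotations(bad), "Mediumish")

  expect_error(parse_protein_annotations(path, target_slide_count = 0),
               "positive")
})

test_that("largest_remainder_round always hits the target total", {
  set.seed(5)
  for (i in 1:50) {
    cnt <- rpois(4, 5) + c(1, 0, 0, 0)
    total <- sample(1:120, 1)
    out <- largest_remainder_round(cnt, total)
    expect_equal(sum(out), total)
    expect_true(all(out >= 0))
  }
})
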