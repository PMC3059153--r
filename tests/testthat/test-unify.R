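# helpers building small multi-platform gene-summary sets in memory

make_platform_set <- function(lambda_by_gene, n = 150, seed = 1,
                              platforms = c("u133", "exon", "agilent")) {
  set.seed(seed)
  genes <- names(lambda_by_gene)
  mats <- lapply(platforms, function(p) NULL)
  names(mats) <- platforms
  samples <- paste0("s", seq_len(n))
  for (g in genes) {
    y <- sim_from_lambda(lambda_by_gene[[g]], n,
                         seed = seed + match(g, genes))
    for (k in seq_along(platforms)) {
      row <- matrix(6 + y[k, ], 1, dimnames = list(g, samples))
      mats[[k]] <- rbind(mats[[k]], row)
    }
  }
  mats
}

test_that("perfectly concordant platforms give near-unit loadings", {
  n <- 100
  set.seed(5)
  v <- rnorm(n)
  samples <- paste0("s", seq_len(n))
  row <- matrix(8 + v, 1, dimnames = list("geneA", samples))
  ue <- unify_gene_level(list(a = row, b = row, c = row))
  rec <- ue$genes[["geneA"]]
  expect_true(all(rec$loadings >= 0.99))
  expect_gt(cor(rec$scores, v), 0.999)
  expect_true(rec$heywood)  # exact concordance is a boundary fit
})

test_that("a discordant platform is down-weighted and scores track the others", {
  mats <- make_platform_set(list(g1 = c(0.9, 0.9, 0.1)), n = 200, seed = 7)
  ue <- unify_gene_level(mats)
  rec <- ue$genes[["g1"]]
  expect_lt(rec$loadings["agilent"], min(rec$loadings[c("u133", "exon")]))
  std <- standardize(do.call(rbind, lapply(mats, function(m) m["g1", ])))
  cors <- abs(apply(std$values, 1, cor, y = rec$scores))
  expect_equal(unname(which.min(cors)), 3L)
})

test_that("genes on fewer than three platforms land in the skipped report", {
  mats <- make_platform_set(list(g1 = c(.8, .8, .8), g2 = c(.8, .8, .8)),
                            n = 60, seed = 2)
  mats$agilent <- mats$agilent["g1", , drop = FALSE]  # g2 only on 2 platforms
  ue <- unify_gene_level(mats)
  expect_true("g2" %in% ue$skipped$gene_id)
  expect_match(ue$skipped$reason[ue$skipped$gene_id == "g2"], "2 platform")
  expect_false("g2" %in% ue$gene_ids)
  expect_true("g1" %in% ue$gene_ids)
})

test_that("sample-ID mismatches across platforms are fatal and named", {
  mats <- make_platform_set(list(g1 = c(.8, .8, .8)), n = 30, seed = 3)
  colnames(mats$exon)[1] <- "rogue_sample"
  expect_error(unify_gene_level(mats), "rogue_sample")
})

test_that("sample alignment is by ID, not column order", {
  mats <- make_platform_set(list(g1 = c(.9, .9, .9)), n = 50, seed = 4)
  shuffled <- mats
  perm <- sample(ncol(shuffled$exon))
  shuffled$exon <- shuffled$exon[, perm, drop = FALSE]
  expect_equal(unify_gene_level(shuffled)$genes[["g1"]]$scores,
               unify_gene_level(mats)$genes[["g1"]]$scores)
})

test_that("unify_gene_level is deterministic", {
  mats <- make_platform_set(list(g1 = c(.9, .8, .7), g2 = c(.6, .6, .6)),
                            n = 80, seed = 6)
  u1 <- unify_gene_level(mats)
  u2 <- unify_gene_level(mats)
  expect_identical(u1$scores, u2$scores)
})

test_that("high pairwise correlation regime gives strong loadings everywhere", {
  # all pairwise platform correlations > 0.9
  mats <- make_platform_set(
    list(hg1 = c(.97, .96, .97), hg2 = c(.98, .97, .96)), n = 200, seed = 8)
  ue <- unify_gene_level(mats)
  for (g in c("hg1", "hg2")) {
    rec <- ue$genes[[g]]
    raw <- do.call(rbind, lapply(mats, function(m) m[g, ]))
    expect_gt(min(cor(t(raw))[upper.tri(diag(3))]), 0.9)
    expect_true(all(rec$loadings > 0.8))
    cors <- apply(raw, 1, cor, y = rec$scores)
    expect_true(all(abs(cors) > 0.9))
  }
})

test_that("down-weighting holds in distribution over many simulated genes", {
  lam <- c(0.9, 0.9, 0.1)
  hats <- t(vapply(1:40, function(i) {
    std <- standardize(sim_from_lambda(lam, 200, seed = 300 + i))
    fit_em(std)$loadings
  }, numeric(3)))
  expect_lt(median(hats[, 3]), 0.35)
  expect_gt(median(hats[, 1]), 0.8)
  expect_gt(median(hats[, 2]), 0.8)
})

# --- probe level ---

make_probe_set <- function(spec, n = 120, seed = 1) {
  # spec: list(gene = list(platform = list(k, lambda_range, latent_id)))
  set.seed(seed)
  latents <- new.env()
  rows <- NULL
  ann <- NULL
  samples <- paste0("s", seq_len(n))
  for (g in names(spec)) {
    for (pl in names(spec[[g]])) {
      cfg <- spec[[g]][[pl]]
      key <- cfg$latent %||% g
      if (is.null(latents[[key]])) latents[[key]] <- rnorm(n)
      f <- latents[[key]]
      for (j in seq_len(cfg$k)) {
        lam <- runif(1, cfg$range[1], cfg$range[2])
        e <- rnorm(n) * sqrt(max(1 - lam^2, 1e-4))
        id <- sprintf("%s_%s_%02d", g, pl, j)
        rows <- rbind(rows, matrix(5 + lam * f + e, 1,
                                   dimnames = list(id, samples)))
        ann <- rbind(ann, data.frame(probe_id = id, gene_id = g,
                                     platform = pl, copies = 1L))
      }
    }
  }
  list(probes = rows, ann = ann, latents = latents)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("concordant probes recover the latent profile", {
  ps <- make_probe_set(list(gA = list(
    u133 = list(k = 5, range = c(.9, .97)),
    exon = list(k = 5, range = c(.9, .97)))), n = 120, seed = 10)
  ue <- unify_probe_level(ps$probes, ps$ann)
  rec <- ue$genes[["gA"]]
  expect_true(all(rec$loadings > 0.85))
  expect_gt(abs(cor(rec$scores, ps$latents[["gA"]])), 0.99)
  expect_named(rec$per_platform_median_loading, c("exon", "u133"),
               ignore.order = TRUE)
})

test_that("a majority platform of discordant probes drives the scores", {
  ps <- make_probe_set(list(gB = list(
    u133 = list(k = 8, range = c(.85, .95), latent = "minor"),
    agilent = list(k = 2, range = c(.85, .95), latent = "minor"),
    exon = list(k = 40, range = c(.85, .95), latent = "major"))),
    n = 150, seed = 11)
  ue <- unify_probe_level(ps$probes, ps$ann)
  rec <- ue$genes[["gB"]]
  r_major <- abs(cor(rec$scores, ps$latents[["major"]]))
  r_minor <- abs(cor(rec$scores, ps$latents[["minor"]]))
  expect_gt(r_major, r_minor)
  expect_gt(r_major, 0.9)
})

test_that("single-probe and underdetermined genes are skipped with reasons", {
  ps <- make_probe_set(list(
    gC = list(u133 = list(k = 1, range = c(.8, .9))),
    gD = list(exon = list(k = 30, range = c(.8, .9)))), n = 25, seed = 12)
  ue <- unify_probe_level(ps$probes, ps$ann)
  expect_match(ue$skipped$reason[ue$skipped$gene_id == "gC"], "1 probe")
  expect_equal(ue$skipped$reason[ue$skipped$gene_id == "gD"],
               "underdetermined")
  expect_length(ue$gene_ids, 0)
})

test_that("probe-count minimums per platform are checkable", {
  ps <- make_probe_set(list(gE = list(
    u133 = list(k = 4, range = c(.8, .9)),
    agilent = list(k = 3, range = c(.8, .9)))), n = 40, seed = 13)
  bad <- check_probe_annotation(ps$ann, min_probes = c(u133 = 5, agilent = 3))
  expect_equal(bad$gene_id, "gE")
  expect_equal(bad$platform, "u133")
  expect_equal(bad$n_probes, 4L)
  ok <- check_probe_annotation(ps$ann, min_probes = 3)
  expect_equal(nrow(ok), 0L)
})

test_that("qc_classify flags follow the thresholds deterministically", {
  th <- gene_qc_thresholds(min_median_expression = 4, min_iqr = 0.5,
                           low_loading_cutoff = 0.5)
  raw_hi <- matrix(rep(c(8, 9, 7), 50), 3, 50) + matrix(rnorm(150), 3)
  expect_true("negative_loading" %in%
                qc_classify(c(.9, .9, -.2), raw_hi, thresholds = th))
  expect_true("low_loading" %in%
                qc_classify(c(.95, .9, .3), raw_hi, thresholds = th))
  expect_length(qc_classify(c(.95, .9, .8), raw_hi, thresholds = th), 0)
  flat <- matrix(5, 3, 50)
  expect_true("low_iqr" %in% qc_classify(c(.9, .9, .9), flat, thresholds = th))
  low <- raw_hi - 6
  expect_true("low_expression" %in%
                qc_classify(c(.9, .9, .9), low, thresholds = th))
  # per-platform background cutoffs
  th2 <- gene_qc_thresholds(
    min_median_expression = c(u133 = 4, exon = 4, agilent = 0))
  raw_mixed <- rbind(u133 = rnorm(50, 8), exon = rnorm(50, 8),
                     agilent = rnorm(50, 1))
  expect_false("low_expression" %in%
                 qc_classify(c(.9, .9, .9), raw_mixed,
                             rownames(raw_mixed), th2))
})

test_that("gene-level vs probe-level score comparison is sign-aligned", {
  x <- rnorm(50)
  expect_equal(compare_gene_vs_probe(x, x), 1.0)
  expect_equal(compare_gene_vs_probe(x, -x), 1.0)
  set.seed(21)
  r_null <- compare_gene_vs_probe(rnorm(400), rnorm(400))
  expect_lt(r_null, 3 / sqrt(400))
  expect_warning(r_const <- compare_gene_vs_probe(rep(1, 50), x), "constant")
  expect_true(is.na(r_const))
})

test_that("gene-level and probe-level scores agree for most well-behaved genes", {
  # shared latent factor, moderate probe noise, probe counts 6/10/3
  set.seed(30)
  n <- 120
  n_genes <- 20
  agree <- vapply(seq_len(n_genes), function(i) {
    ps <- make_probe_set(stats::setNames(list(list(
      u133 = list(k = 6, range = c(.6, .9)),
      exon = list(k = 10, range = c(.6, .9)),
      agilent = list(k = 3, range = c(.6, .9)))), paste0("g", i)),
      n = n, seed = 500 + i)
    pue <- unify_probe_level(ps$probes, ps$ann)
    summaries <- lapply(split(ps$ann$probe_id, ps$ann$platform),
                        function(ids) {
      matrix(colMeans(ps$probes[ids, , drop = FALSE]), 1,
             dimnames = list(paste0("g", i), colnames(ps$probes)))
    })
    gue <- unify_gene_level(summaries)
    compare_gene_vs_probe(gue$genes[[1]]$scores, pue$genes[[1]]$scores)
  }, numeric(1))
  expect_gte(mean(agree > 0.8), 0.7)
})
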