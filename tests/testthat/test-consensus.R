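mk_result <- function(method, ranks) {
  refstab:::new_stability_result(method, stats::setNames(as.numeric(ranks), names(ranks)),
                                 ranks, "lower is better")
}

test_that("geometric-mean aggregation reproduces hand-checked panel rows", {
  # three methods ranking a gene 8, 8, 2 -> geo mean 5.04 -> mid-panel rank
  genes <- letters[1:8]
  gn <- stats::setNames(c(1, 3, 6, 4, 7, 5, 2, 8L), genes)
  nf <- stats::setNames(c(1, 3, 7, 6, 5, 4, 2, 8L), genes)
  bk <- stats::setNames(c(1, 5, 7, 6, 8, 4, 3, 2L), genes)
  cons <- comprehensive_rank(list(mk_result("genorm", gn),
                                  mk_result("normfinder", nf),
                                  mk_result("bestkeeper", bk)))
  tab <- cons$table
  expect_equal(tab$geo_mean_rank[tab$gene == "h"], (8 * 8 * 2)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(tab$comprehensive_rank[tab$gene == "h"], 5L)
  # (2, 3, 4) -> geo mean 2.884
  expect_equal((2 * 3 * 4)^(1 / 3), 2.884, tolerance = 1e-3)
})

test_that("consensus is idempotent for agreeing methods and single method", {
  genes <- paste0("g", 1:5)
  rk <- stats::setNames(c(3L, 1L, 5L, 2L, 4L), genes)
  cons <- comprehensive_rank(list(mk_result("genorm", rk), mk_result("normfinder", rk)))
  expect_equal(stats::setNames(cons$table$comprehensive_rank, cons$table$gene)[genes],
               rk)
  one <- comprehensive_rank(list(mk_result("bestkeeper", rk)))
  expect_equal(stats::setNames(one$table$comprehensive_rank, one$table$gene)[genes], rk)
})

test_that("permutation equivariance and contract errors", {
  mat <- cbind(m1 = c(1, 2, 3, 4), m2 = c(2, 1, 4, 3))
  rownames(mat) <- c("w", "x", "y", "z")
  cons <- comprehensive_rank(mat)
  perm <- c(3, 1, 4, 2)
  cons2 <- comprehensive_rank(mat[perm, ])
  expect_equal(stats::setNames(cons2$table$comprehensive_rank, cons2$table$gene),
               stats::setNames(cons$table$comprehensive_rank, cons$table$gene)[perm])

  bad <- mk_result("normfinder", stats::setNames(1:4, c("w", "x", "y", "QQ")))
  expect_error(comprehensive_rank(list(mk_result("genorm",
                                                 stats::setNames(1:4, c("w", "x", "y", "z"))),
                                       bad)),
               "QQ", class = "refstab_contract_error")
})

test_that("ties break by mean rank then gene name and are reported", {
  mat <- cbind(m1 = c(1, 2, 4, 3), m2 = c(4, 2, 1, 3))   # genes a,b have geo 2, 2
  rownames(mat) <- c("a", "b", "c", "d")
  cons <- comprehensive_rank(mat)
  expect_true(all(cons$tied[c("a", "b", "c")]))
  tab <- cons$table
  # a and c: geo = 2, mean 2.5; b: geo = 2, mean 2 -> b first, then a before c by name
  expect_equal(tab$comprehensive_rank[match(c("b", "a", "c", "d"), tab$gene)],
               c(1L, 2L, 3L, 4L))
})

test_that("recommendation fills from consensus, honours exclusions and audits", {
  pub <- published_table("rankings")
  sugg <- published_table("suggestions")
  panel <- function(sp, ti) {
    sub <- pub[pub$species == sp & pub$tissue == ti, ]
    mat <- as.matrix(sub[, c("genorm_rank", "normfinder_rank", "bestkeeper_rank")])
    rownames(mat) <- sub$gene
    comprehensive_rank(mat)
  }
  # two-gene panels: top-2 of the consensus reproduces every published suggestion
  for (i in which(sugg$species != "piceifrons")) {
    cons <- panel(sugg$species[i], sugg$tissue[i])
    rec <- recommend_references(cons, 2)
    expect_equal(rec$recommended, c(sugg$gene1[i], sugg$gene2[i]),
                 info = paste(sugg$species[i], sugg$tissue[i]))
  }
  # condition-responsive exclusions, three genes: head panel
  rec <- recommend_references(panel("piceifrons", "head"), 3,
                              exclusions = c(Ann = "condition-responsive",
                                             Act5C = "condition-responsive",
                                             Arm = "condition-responsive",
                                             Tub = "least stable overall"))
  expect_equal(rec$recommended, c("RIBL5", "Hsp70", "EF2"))
  expect_length(rec$audit, 6)   # 3 skips + 3 inclusions before the list fills

  # documented override: force-include a low-consensus gene, thorax panel
  rec2 <- recommend_references(panel("piceifrons", "thorax"), 3,
                               exclusions = c(Ann = "condition-responsive",
                                              Act5C = "condition-responsive",
                                              Arm = "condition-responsive",
                                              EF2 = "condition-responsive",
                                              Tub = "condition-responsive"),
                               force_include = "RIBL5")
  expect_equal(rec2$recommended, c("RIBL5", "Hsp70", "GAPDH"))
  expect_match(rec2$audit[1], "forced")

  # infeasible exclusions error
  expect_error(recommend_references(panel("nitens", "head"), 7,
                                    exclusions = c(Ann = "x", Act5C = "y")),
               class = "refstab_insufficient_data")
})

test_that("group diagnostic backs condition-responsiveness with delta-Cq and p", {
  cq <- matrix(22, 10, 3, dimnames = list(sprintf("s%d", 1:10), c("a", "b", "c")))
  cq <- cq + with_seed(41, rnorm(30, 0, 0.1))
  cq[6:10, "b"] <- cq[6:10, "b"] + 2
  ds <- make_ds(cq, rep(c("isolated", "crowded"), each = 5))
  diag <- refstab:::group_shift_diagnostic(ds)
  expect_equal(diag$delta_cq[diag$gene == "b"], 2, tolerance = 0.3)
  expect_lt(diag$p_value[diag$gene == "b"], 0.01)
  expect_gt(min(diag$p_value[diag$gene != "b"]), 0.05)
})
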