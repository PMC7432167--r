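test_that("fragment enumeration matches hand counts on simple chains", {
  ethane <- enumerate_fragments("[CH3:1][CH3:2]>>[CH3:1][CH3:2]")
  expect_length(ethane, 1L)
  expect_equal(unname(ethane), 1L)

  butane <- enumerate_fragments("[CH3:1][CH2:2][CH2:3][CH3:4]>>[CH3:1][CH2:2][CH2:3][CH3:4]")
  sizes <- (lengths(regmatches(names(butane), gregexpr("*", names(butane),
                                                       fixed = TRUE))) + 2) / 2
  expect_equal(as.vector(tapply(butane, sizes, sum)), c(3L, 2L, 1L))
})

test_that("fragments cross dynamic bonds with order-change tokens", {
  fr <- enumerate_fragments("[CH3:1][Br:2].[OH-:3]>>[CH3:1][OH:3].[Br-:2]")
  expect_true("Br*single>>none*C*none>>single*O" %in% names(fr))
  # zwitterion fragments carry no charge information, only elements and orders
  z <- enumerate_fragments(paste0("[NH3+:1][CH2:2][C:3](=[O:4])[O-:5]>>",
                                  "[NH2:1][CH2:2][C:3](=[O:4])[OH:5]"))
  expect_false(any(grepl(";", names(z), fixed = TRUE)))
  expect_true("C*single>>single*N" %in% names(z))
})

test_that("total path counts match a brute-force enumeration oracle", {
  suites <- builtin_suites()
  reactions <- unlist(lapply(names(suites), function(nm)
    generate_reactions(suites[[nm]], n = 3, seed = 9)$reaction))
  for (smi in reactions) {
    g <- build_cgr(smi)
    if (nrow(g$atoms) > 12) next
    expect_equal(sum(enumerate_fragments(g)), path_count_oracle(g))
  }
  # a branched fixture
  iso <- "[CH3:1][CH:2]([CH3:3])[CH2:4][OH:5]>>[CH3:1][CH:2]([CH3:3])[CH2:4][OH:5]"
  expect_equal(sum(enumerate_fragments(iso)), path_count_oracle(build_cgr(iso)))
})

test_that("condition vectors assemble solvent, 1/T and molar ratio", {
  v <- condition_vector("water", 298.15, 100)
  expect_length(v, 17L)
  expect_equal(unname(v["inv_T"]), 1 / 298.15, tolerance = 1e-12)
  expect_equal(unname(v["molar_ratio"]), 100)
  expect_error(condition_vector("xylol", 298), "unknown solvent")
  expect_error(condition_vector("water", -3), "positive")
  ex <- condition_vector(seq_len(15), 300, 50)
  expect_equal(unname(ex[1:15]), as.numeric(1:15))
})

test_that("descriptor fit/transform keeps vocabulary, order and unseen report", {
  d <- suite_sample("substitution", 20, seed = 5)
  fit <- reaction_descriptors(d)
  expect_equal(colnames(fit$x), c(fit$vocab, condition_names()))
  expect_equal(fit$vocab, sort(fit$vocab))

  # transform of training rows reproduces the fitted block, nothing unseen
  tp <- predict(fit, d)
  expect_equal(unname(tp$x), unname(fit$x), tolerance = 1e-12)
  expect_true(all(lengths(tp$unseen) == 0L))

  # duplicated reactions give identical rows
  d2 <- d[c(1, 1), ]
  tp2 <- predict(fit, d2)
  expect_equal(tp2$x[1, ], tp2$x[2, ])

  # a reaction with a novel element reports unseen fragments
  novel <- d[1, ]
  novel$reaction <- "[CH3:4][CH2:1][I:2].[OH-:3]>>[CH3:4][CH2:1][OH:3].[I-:2]"
  tp3 <- predict(fit, novel)
  expect_gt(length(tp3$unseen[[1]]), 0L)
  expect_true(any(grepl("I", tp3$unseen[[1]])))

  # one-reaction dataset: its own fragments plus the condition block
  f1 <- reaction_descriptors(d[1, ])
  expect_equal(ncol(f1$x), length(f1$vocab) + 17L)
})

test_that("standardization is population-sd based, degenerate-safe and idempotent", {
  x <- matrix(c(1, 3, 5, 5), 2, 2)
  ctr <- colMeans(x)
  sdp <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  z <- reactAD:::standardize_block(x, ctr, sdp)
  expect_equal(z[, 1], c(-1, 1))        # two-point column, population sd = 1
  expect_equal(z[, 2], c(0, 0))         # constant column maps to zero

  d <- suite_sample("elimination", 25, seed = 6)
  fit <- reaction_descriptors(d)
  expect_lt(max(abs(colMeans(fit$x))), 1e-12)
  sds <- sqrt(colMeans(sweep(fit$x, 2, colMeans(fit$x))^2))
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-12))
  # standardizing an already standardized block changes nothing
  z2 <- reactAD:::standardize_block(fit$x, colMeans(fit$x),
                                    sqrt(colMeans(sweep(fit$x, 2, colMeans(fit$x))^2)))
  expect_equal(z2[, sds > 0], fit$x[, sds > 0], tolerance = 1e-12)
})

test_that("dataset round-trips through the delimited file format", {
  d <- suite_sample("cycloaddition", 10, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back$reaction, d$reaction)
  expect_equal(back$property, d$property, tolerance = 1e-12)
  expect_equal(attr(back, "flags")$planted_outlier,
               attr(d, "flags")$planted_outlier)
  unlink(c(path, paste0(path, ".flags.csv")))
})
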