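test_that("transition graph counts consecutive state pairs", {
  dw <- data.frame(state = rep(c(1, 2), 5)[1:9], t_start = 0:8,
                   duration = 1, mean_force = 10)
  g <- build_transition_graph(dw)
  expect_identical(g[1, 2] + g[2, 1], 8L)
  expect_identical(diag(g), c(0L, 0L))
  # row sums equal per-state dwell counts minus the terminal dwell
  expect_identical(unname(rowSums(g)), c(4, 4))
  expect_error(build_transition_graph(dw[dw$state == 1, ]), "2 states")
})

test_that("pendant states are classified off-pathway", {
  # linear chain 1-2-3: everything on-pathway
  g <- matrix(0L, 3, 3)
  g[1, 2] <- g[2, 1] <- 10L; g[2, 3] <- g[3, 2] <- 10L
  cl <- classify_off_pathway(g)
  expect_true(all(cl$classification == "on_pathway"))
  # pendant state 4 attached to 2 only
  g2 <- matrix(0L, 4, 4)
  g2[1, 2] <- g2[2, 1] <- 10L; g2[2, 3] <- g2[3, 2] <- 10L
  g2[2, 4] <- g2[4, 2] <- 5L
  cl2 <- classify_off_pathway(g2, terminals = c(1, 3))
  expect_identical(cl2$classification[4], "off_pathway")
  expect_true(all(cl2$classification[1:3] == "on_pathway"))
  # sub-threshold second partner is reported for sensitivity
  g3 <- g2; g3[4, 3] <- 2L; g3[3, 4] <- 0L
  cl3 <- classify_off_pathway(g3, terminals = c(1, 3))
  expect_identical(cl3$classification[4], "off_pathway")
  expect_match(cl3$near_miss_partners[4], "3")
  # disconnection is an error listing components
  g4 <- matrix(0L, 4, 4); g4[1, 2] <- g4[2, 1] <- 10L
  g4[3, 4] <- g4[4, 3] <- 10L
  expect_error(classify_off_pathway(g4), "disconnected")
})

test_that("misfold detection succeeds on nearly every simulated path", {
  p <- otfold_preset("ADE_six_state")
  hits <- vapply(1:30, function(s) {
    path <- simulate_state_path(
      p$scheme, duration = 25, seed = 300 + s,
      force_of_state = otfold:::scheme_state_forces(p$scheme, p$model,
                                                    p$trap_separation))
    if (nrow(path) < 200) return(NA)   # want >= 200 transitions
    idx <- match(path$state, ade_level_names)
    dw <- data.frame(state = idx, t_start = path$t_start,
                     duration = path$duration, mean_force = 10)
    g <- build_transition_graph(dw, n_states = 6)
    cl <- tryCatch(classify_off_pathway(g), error = function(e) NULL)
    if (is.null(cl)) return(FALSE)
    identical(cl$classification,
              ifelse(ade_level_names == "M", "off_pathway", "on_pathway"))
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("unzipping enumeration walks the hairpin outside-in", {
  m <- elastic_model()
  # toy hairpin (((....))): one helix, full release of 10 nt
  s <- secondary_structure("GGGAAAACCC", "(((....)))")
  e <- enumerate_unzipping_intermediates(s, m)
  expect_identical(nrow(e), 1L)
  expect_identical(e$n_unfolded_nt, 10)
  expect_equal(e$expected_delta_contour, 10 * 0.65 - 2.0)
  # two helices with an interior bulge: exactly 2 intermediates
  s2 <- secondary_structure("GGGAGGAAAACCACCC", "(((.((....)).)))")
  e2 <- enumerate_unzipping_intermediates(s2, m)
  expect_identical(nrow(e2), 2L)
  expect_identical(e2$n_unfolded_nt, c(8, 16))
  # last intermediate always releases the whole fragment
  expect_equal(e2$n_unfolded_nt[2], nchar(s2$sequence))
  # fixture hairpins
  ecde <- enumerate_unzipping_intermediates(cde_hairpin(), m)
  expect_identical(ecde$n_unfolded_nt, 15)
  eade <- enumerate_unzipping_intermediates(ade_hairpin(), m)
  expect_identical(eade$n_unfolded_nt, c(14, 26, 38, 52))
  # multibranch structures are rejected
  s3 <- secondary_structure("GGAAACCGGAAACC", "((...))((...))")
  expect_error(enumerate_unzipping_intermediates(s3, m), "unsupported")
})

test_that("observed gains map to intermediates; misfits become misfold candidates", {
  m <- elastic_model()
  enum <- enumerate_unzipping_intermediates(ade_hairpin(), m)
  # identity match
  mm <- match_intermediates(enum$expected_delta_contour, enum)
  expect_identical(mm$matched_intermediate, enum$intermediate)
  expect_true(all(!mm$misfold_candidate))
  # the six-state fixture: I1/I2/I3/U gains match, M's does not
  p <- otfold_preset("ADE_six_state")
  obs_nt <- c(14, 26, 38, 52, 7)
  obs <- ifelse(obs_nt == 52, obs_nt * 0.65 - 2, obs_nt * 0.65)
  mm2 <- match_intermediates(obs, enum)
  expect_identical(mm2$matched_intermediate[1:4], 1:4)
  expect_true(mm2$misfold_candidate[5])
  # a value between two candidates within tolerance is flagged ambiguous
  mid <- mean(enum$expected_delta_contour[1:2])
  mm3 <- match_intermediates(mid, enum, tolerance = 5)
  expect_true(mm3$ambiguous)
  expect_error(match_intermediates(numeric(0), enum), "non-empty")
})

test_that("competing candidate structures are ranked by residuals", {
  m <- elastic_model()
  obs <- enumerate_unzipping_intermediates(ade_hairpin(),
                                           m)$expected_delta_contour
  rank <- compare_structures(obs,
                             list(ade = ade_hairpin(),
                                  cde = cde_hairpin()), m)
  expect_identical(rank$structure[1], "ade")
  expect_lt(rank$total_abs_residual[1], rank$total_abs_residual[2])
})

test_that("dot-bracket parsing validates balance and alphabet", {
  expect_error(secondary_structure("GGG", "((("), "unbalanced")
  expect_error(secondary_structure("GGGA", "()))"), "unbalanced")
  expect_error(secondary_structure("GGX", "..."), "AUGC")
  expect_error(secondary_structure("GG", "..."), "lengths differ")
  s <- secondary_structure("gcaagc", "((..))", numbering_offset = 52)
  expect_identical(s$sequence, "GCAAGC")
  expect_identical(s$numbering_offset, 52)
  expect_identical(nrow(s$pairs), 2L)
})
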