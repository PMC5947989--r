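test_that("morphology validation rejects malformed trees", {
  ok <- tibble::tibble(comp = 1:3, parent = 0:2, length_um = 10, diam_um = 2,
                       region = "trunk")
  expect_s3_class(neuron_morphology(ok), "neuron_morphology")
  bad_order <- ok; bad_order$parent <- c(0, 3, 1)
  expect_error(neuron_morphology(bad_order), "ordered")
  two_roots <- ok; two_roots$parent <- c(0, 0, 2)
  expect_error(neuron_morphology(two_roots), "root")
  bad_diam <- ok; bad_diam$diam_um[2] <- 0
  expect_error(neuron_morphology(bad_diam), "positive")
  bad_region <- ok; bad_region$region <- "soma"
  expect_error(neuron_morphology(bad_region), "region")
})

test_that("SWC files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c(
    "# synthetic three-point morphology",
    "1 1 0 0 0 3 -1",
    "2 4 0 50 0 2 1",
    "3 3 0 110 0 1 2",
    "4 3 30 140 0 1 3",
    "5 3 -30 140 0 1 3"), path)
  m <- read_swc(path)
  expect_equal(nrow(m), 4)
  expect_equal(m$region, c("trunk", "fieldA", "fieldA", "fieldA"))
  expect_equal(m$length_um[1], 50)
  expect_equal(m$length_um[3], sqrt(30^2 + 30^2), tolerance = 1e-9)
  expect_equal(m$diam_um, c(4, 2, 2, 2))
  expect_equal(m$parent, c(0, 1, 2, 2))
  # unmapped type codes are an error
  writeLines(c("1 9 0 0 0 1 -1", "2 9 0 10 0 1 1"), path)
  expect_error(read_swc(path), "mapping")
})

test_that("model assembly wires regions, gradients and calibration", {
  model <- reference_model()
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("gbar_HCN", "gbar_KD", "gbar_Na") %in% names(td)))
  # no fast Na+ in dendrites, HCN/KD confined to field A
  expect_true(all(td$gbar_Na[td$region == "fieldA"] == 0))
  expect_true(all(td$gbar_HCN[td$region != "fieldA"] == 0))
  # density gradient increases toward distal endings
  ia <- comps_in_region(model, "fieldA")
  dens <- model$density_mat[ia, "HCN"] / model$area_cm2[ia] * 0 +
    model$density_mat[ia, "HCN"]
  expect_gt(stats::cor(model$path_um[ia], dens), 0.9)
  # resting potential equals the calibration target
  expect_equal(loomsel:::steady_rmp(model, siz_comp(model)), -65,
               tolerance = 0.01)
  gl <- glance(model)
  expect_equal(gl$n_field_a, 120)
})

test_that("blockade scales conductances without recalibrating rest", {
  model <- reference_model()
  blocked <- set_channel_block(model, HCN = 0, KD = 0.5)
  expect_equal(blocked$block[["HCN"]], 0)
  expect_equal(blocked$block[["KD"]], 0.5)
  expect_identical(blocked$e_leak, model$e_leak)
  expect_error(set_channel_block(model, XYZ = 0))
  # a pure HCN block hyperpolarizes the resting potential
  expect_lt(loomsel:::steady_rmp(set_channel_block(model, HCN = 0),
                                 siz_comp(model)),
            loomsel:::steady_rmp(model, siz_comp(model)) - 0.5)
})
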