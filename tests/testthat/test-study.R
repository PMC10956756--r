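# End-to-end pipeline: artifacts, manifest and bit-level determinism on a
# small study (coarse mesh, no-surgery + one repair, calibration disabled
# so the configured magnitudes are used directly).

small_cfg <- function(dir) {
  validate_config(list(
    geometry = list(target_edge_length = 9),
    calibration = list(enabled = FALSE),
    surgery_matrix = list(
      list(sides = character(0), anchor_distance_mm = 20),
      list(sides = "left", anchor_distance_mm = 20)),
    output = list(dir = dir)))
}

test_that("run_study writes reports, snapshots and a complete manifest", {
  d1 <- file.path(tempdir(), "study_a")
  st <- run_study(small_cfg(d1), quiet = TRUE)

  expect_s3_class(st$report, "descent_report")
  expect_equal(nrow(st$report), 2)
  expect_true(all(st$report$converged))
  # surgery reduces the apical descent at the same load
  expect_lt(st$report$C_mm[2], st$report$C_mm[1])
  # report rows are keyed without duplicates
  expect_false(anyDuplicated(st$report[, c("sides", "anchor_distance_mm")]) > 0)

  expect_true(file.exists(st$paths$csv))
  expect_true(file.exists(st$paths$json))
  expect_true(file.exists(st$paths$geometry))
  expect_true(all(file.exists(st$paths$stl)))
  expect_length(st$paths$vtk, 2)
  expect_true(all(file.exists(st$paths$vtk)))

  # manifest lists every artifact with a checksum that matches the file
  man <- jsonlite::read_json(st$paths$manifest, simplifyVector = FALSE)
  expect_equal(man$seed, 1)
  for (a in man$artifacts) {
    expect_true(file.exists(a$path))
    expect_identical(unname(tools::md5sum(a$path)), a$md5)
  }

  # rerunning the same configuration reproduces the report bit-identically
  d2 <- file.path(tempdir(), "study_b")
  st2 <- run_study(small_cfg(d2), quiet = TRUE)
  expect_identical(readLines(st$paths$csv), readLines(st2$paths$csv))
  unlink(c(d1, d2), recursive = TRUE)
})
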