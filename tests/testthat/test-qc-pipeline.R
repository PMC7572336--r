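make_manifest <- function(n, n_mening = 0, n_artif = 0, overlap = FALSE) {
  m <- tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(n)),
    qc_meningioma = FALSE, qc_artifact = FALSE
  )
  if (n_mening > 0) m$qc_meningioma[seq_len(n_mening)] <- TRUE
  if (n_artif > 0) {
    from <- if (overlap) 1L else n_mening + 1L
    m$qc_artifact[from:(from + n_artif - 1L)] <- TRUE
  }
  m
}

test_that("QC exclusions reproduce the 608 - 10 - 37 = 561 arithmetic", {
  qc <- apply_qc(make_manifest(608, 10, 37))
  expect_equal(nrow(qc$included), 561L)
  rep <- qc$report
  expect_equal(rep$n_excluded[rep$reason == "meningioma"], 10L)
  expect_equal(rep$n_excluded[rep$reason == "artifact_or_segmentation_failure"], 37L)
  # conservation: included + per-reason tallies = manifest rows
  expect_equal(sum(rep$n_excluded[rep$reason %in%
                                    c("meningioma", "artifact_or_segmentation_failure", "included")]),
               rep$n_excluded[rep$reason == "total"])
})

test_that("flag-free manifests pass through and double flags follow precedence", {
  qc <- apply_qc(make_manifest(25))
  expect_equal(nrow(qc$included), 25L)
  # one subject with both flags in a 3-row toy: excluded once, as meningioma
  m <- make_manifest(3, n_mening = 1, n_artif = 1, overlap = TRUE)
  qc2 <- apply_qc(m)
  expect_equal(nrow(qc2$included), 2L)
  expect_equal(qc2$report$n_excluded[qc2$report$reason == "meningioma"], 1L)
  expect_equal(qc2$report$n_excluded[qc2$report$reason == "artifact_or_segmentation_failure"], 0L)
})

test_that("manifest defects are rejected", {
  m <- make_manifest(4)
  m$subject_id[2] <- m$subject_id[1]
  expect_error(apply_qc(m), class = "bullseye_manifest_error")
  expect_error(apply_qc(make_manifest(0)), class = "bullseye_input_error")
  expect_error(apply_qc(tibble::tibble(subject_id = "a")),
               class = "bullseye_manifest_error")
})

test_that("unknown pipeline configuration keys fail before any computation", {
  expect_error(pipeline_config(n_phntoms = 3), class = "bullseye_schema_error")
  expect_error(pipeline_config(phantom = list(lesion_cnt = 3)),
               class = "bullseye_schema_error")
})

test_that("the pipeline runs end to end and is a no-op on identical re-runs", {
  out_dir <- withr::local_tempdir()
  cfg <- pipeline_config(
    n_phantoms = 1L,
    phantom = list(grid_shape = c(40L, 40L, 40L), brain_axes = c(17, 14.5, 14.5),
                   ventricle_axes = c(7, 4.5, 4.5), bg_offset = 10,
                   bg_axes = c(3.8, 3.3, 3.3), lesion_count = 3L),
    cohort = list(n_subjects = 120L),
    n_perm = 200L, seed = 3L
  )
  outputs <- suppressMessages(run_wmh_pipeline(cfg, out_dir))
  for (f in c("cohort.csv", "qc_report.csv", "cohort_scored.csv",
              "associations.csv", "phantom_loads.csv", "provenance.json",
              "bullseye_memory_z.svg", "bullseye_memory_z.csv",
              "cross_correlation.svg")) {
    expect_true(file.exists(file.path(out_dir, f)), label = f)
  }
  assoc <- utils::read.csv(file.path(out_dir, "associations.csv"))
  expect_equal(nrow(assoc), 37L * 16L)
  loads <- utils::read.csv(file.path(out_dir, "phantom_loads.csv"))
  expect_lt(abs(sum(loads[, paste0("load_region_", 1:36)]) - loads$load_total),
            1e-6 * max(loads$load_total, 1))

  # identical rerun: provenance hash matches, outputs untouched
  before <- file.mtime(file.path(out_dir, "associations.csv"))
  expect_message(run_wmh_pipeline(cfg, out_dir), "up to date")
  expect_identical(file.mtime(file.path(out_dir, "associations.csv")), before)
})

test_that("bullseye wedge geometry covers 360 degrees with ring radii at layer edges", {
  vals <- bullseye_region_lookup() |>
    dplyr::mutate(rho = seq(-0.3, 0.3, length.out = 36))
  p <- plot_bullseye(vals, value_col = "rho")
  geo <- p$data
  # angular spans per ring sum to 360 degrees
  for (l in 1:4) {
    expect_equal(sum(geo$xmax[geo$layer == l] - geo$xmin[geo$layer == l]), 360)
  }
  expect_setequal(unique(c(geo$ymin, geo$ymax)), c(0, 0.25, 0.5, 0.75, 1))
  # innermost ring is the periventricular layer
  expect_equal(unique(geo$ymin[geo$layer == 1]), 0)

  expect_error(plot_bullseye(vals[1:10, ]), class = "bullseye_parameter_error")
})

test_that("non-significant bullseye cells are neutral and uniform values render uniformly", {
  vals <- bullseye_region_lookup() |>
    dplyr::mutate(rho = 0.2, significant = FALSE)
  p <- plot_bullseye(vals, significant_col = "significant")
  expect_true(all(is.na(p$data$fill_value)))
  vals$significant <- TRUE
  p2 <- plot_bullseye(vals, significant_col = "significant")
  expect_equal(unique(p2$data$fill_value), 0.2)
})

test_that("cross-correlation rendering validates symmetry and round-trips values", {
  tab <- tibble::tibble(a = c(2, 4, 4, 7, 9), b = c(1, 3, 2, 6, 8),
                        c = c(9, 6, 4, 3, 1))
  xc <- cross_correlation(tab, columns = c("a", "b", "c"))
  out <- withr::local_tempfile()
  p <- render_cross_correlation(xc$r, xc$p, out)
  expect_true(file.exists(paste0(out, ".csv")))
  rendered <- utils::read.csv(paste0(out, ".csv"))
  expect_equal(rendered$r[rendered$measure1 == "a" & rendered$measure2 == "b"],
               unname(xc$r["a", "b"]), tolerance = 1e-12)

  bad <- xc$r; bad[1, 2] <- 0.9; bad[2, 1] <- -0.9
  expect_error(render_cross_correlation(bad, xc$p, out),
               class = "bullseye_parameter_error")
})

test_that("association maps render as bullseye panels", {
  coh <- cognitive_composites(simulate_cohort(cohort_spec(n_subjects = 80,
                                                          seed = 33)))
  am <- association_map(coh, outcomes = "memory_z", n_perm = 150, seed = 2)
  p <- autoplot(am, outcome = "memory_z")
  expect_s3_class(p, "ggplot")
  expect_equal(nrow(p$data), 36L)
})
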