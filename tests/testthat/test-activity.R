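# registry with extracted image assets ready for processing
activity_fixture <- function(env = parent.frame(), seed = 7) {
  study <- generate_study(study_spec(seed = seed, violation_rate = 0),
                          withr::local_tempdir(.local_envir = env))
  fx <- fixture_registry(study, archive_dir = withr::local_tempdir(.local_envir = env))
  withr::defer(registry_close(fx$reg), envir = env)
  prot <- protocol_activate(default_t1_protocol("synth"))
  images <- dplyr::bind_rows(purrr::map(fx$batch$archive, function(a) {
    extract_images(fx$reg, a, prot)$assets
  }))
  res <- fixture_resource(fx$reg, root = withr::local_tempdir(.local_envir = env))
  c(fx, list(images = images, res = res))
}

test_that("resources and instances enforce their contracts", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  expect_error(resource_add(reg, "bad", purpose = "processing"), "input and an output")
  resource_add(reg, "drop", purpose = "dropbox")
  fixture_resource(reg, "proc")
  instance_create(reg, "freesurfer", "5.1", "-all", "proc", "synth")
  expect_error(instance_create(reg, "freesurfer", "5.1", "-all", "proc", "synth"),
               "already exists")
  instance_create(reg, "freesurfer", "5.3", "-all", "proc", "synth")  # new version ok
  expect_error(instance_create(reg, "freesurfer", "", "-all", "proc", "synth"),
               "non-empty")
  expect_error(instance_create(reg, "fs", "1", "", "ghost", "synth"), "unknown resource")
})

test_that("requested jobs are staged with precomputed distinct output ids", {
  fx <- activity_fixture()
  instance_create(fx$reg, "freesurfer", "5.1", "-all", fx$res$name, "synth")
  ids <- fx$images$id[1:3]
  jobs <- request_jobs(fx$reg, "freesurfer", "5.1", "-all", ids)
  expect_identical(nrow(jobs), 3L)
  expect_identical(anyDuplicated(jobs$output_id), 0L)
  expect_true(all(jobs$state == "staged"))
  # staging directories named by output id and populated with the inputs
  for (i in 1:3) {
    expect_identical(basename(jobs$staging_dir[i]), jobs$output_id[i])
    expect_gt(length(list.files(jobs$staging_dir[i], recursive = TRUE)), 0L)
  }
  # output id matches the deterministic derivation
  expect_identical(jobs$output_id[1],
                   as.character(derive_output_id("freesurfer", "5.1", "-all", ids[1])))

  # unauthorized project is refused
  project_create(fx$reg, "other", timepoints = "M00")
  register_individuals(fx$reg, data.frame(Project = "other", SiteId = "X1"))
  foreign <- register_asset(fx$reg, derive_id(asset_key("image", "foreign")),
                            "image", project = "other", individual = "X1",
                            timepoint = "M00")
  expect_error(request_jobs(fx$reg, "freesurfer", "5.1", "-all", foreign),
               "not authorized")
})

test_that("completion follows the naming convention and the state machine", {
  fx <- activity_fixture()
  instance_create(fx$reg, "freesurfer", "5.1", "-all", fx$res$name, "synth")
  jobs <- request_jobs(fx$reg, "freesurfer", "5.1", "-all", fx$images$id[1])
  oid <- jobs$output_id[1]

  # a wrongly named upload is rejected and the job unchanged
  stray <- file.path(fx$res$output, "results_final.tar.gz")
  file.create(stray)
  expect_error(complete_job(fx$reg, stray), "naming convention")
  expect_identical(list_jobs(fx$reg)$state, "staged")
  # correctly shaped name but no such job
  ghost <- file.path(fx$res$output, "00000000-0000-0000-0000-000000000000.tar.gz")
  file.create(ghost)
  expect_error(complete_job(fx$reg, ghost), "matches no known job")

  # properly named upload completes the job and registers the collection
  payload <- withr::local_tempdir()
  writeLines("segmentation done", file.path(payload, "result.txt"))
  result <- file.path(fx$res$output, paste0(oid, ".tar.gz"))
  withr::with_dir(payload, utils::tar(result, files = "result.txt",
                                      compression = "gzip", tar = "internal"))
  got <- complete_job(fx$reg, result)
  expect_identical(as.character(got), oid)
  job <- list_jobs(fx$reg)
  expect_identical(job$state, "completed")
  coll <- asset_get(fx$reg, oid)
  expect_identical(coll$kind, "outputCollection")
  # collection inherits assignment from its input
  input <- asset_get(fx$reg, fx$images$id[1])
  expect_identical(coll$project, input$project)
  expect_identical(coll$individual, input$individual)
  expect_identical(coll$timepoint, input$timepoint)

  # duplicate completion is an error
  expect_error(complete_job(fx$reg, result), "already completed")
  # re-requesting the identical processing collides
  expect_error(request_jobs(fx$reg, "freesurfer", "5.1", "-all", fx$images$id[1]),
               "collision")
})

test_that("the local executor captures success, failure, and accounting order", {
  fx <- activity_fixture()
  instance_create(fx$reg, "toolA", "1.0", "", fx$res$name, "synth",
                  stats_member = "stats.txt")
  jobs <- request_jobs(fx$reg, "toolA", "1.0", "", fx$images$id[1:3])

  j1 <- run_local(fx$reg, jobs$output_id[1], stats_template())
  expect_identical(j1$state, "completed")
  expect_identical(j1$exit_code, 0L)
  # declared stats member was parsed into an asset-level collection
  coll <- list_collections(fx$reg)
  expect_true("toolA-1.0" %in% coll$name)
  expect_identical(coll$level[coll$name == "toolA-1.0"], "asset")
  q <- query_scalars(fx$reg, "synth", "toolA-1.0.Hippocampus")
  expect_equal(sum(!is.na(q$`toolA-1.0.Hippocampus`)), 1L)

  j2 <- run_local(fx$reg, jobs$output_id[2], "false")
  expect_identical(j2$state, "failed")
  expect_false(j2$exit_code == 0L)
  expect_error(run_local(fx$reg, jobs$output_id[2], "true"), "not staged")

  summ <- accounting_summary(fx$reg, activity_name = "toolA")
  expect_identical(summ$n[summ$state == "completed"], 1L)
  expect_identical(summ$n[summ$state == "failed"], 1L)
  expect_identical(summ$n[summ$state == "staged"], 1L)
  # ledger preserved in submission order
  ledger <- list_jobs(fx$reg)
  expect_identical(ledger$output_id, jobs$output_id)
})

test_that("provenance traces outputs back to their upload through activity links", {
  fx <- activity_fixture()
  instance_create(fx$reg, "freesurfer", "5.1", "-all", fx$res$name, "synth")
  instance_create(fx$reg, "freesurfer", "5.3", "-all", fx$res$name, "synth")
  img <- fx$images$id[1]
  j51 <- request_jobs(fx$reg, "freesurfer", "5.1", "-all", img)
  j53 <- request_jobs(fx$reg, "freesurfer", "5.3", "-all", img)
  expect_false(identical(j51$output_id, j53$output_id))
  run_local(fx$reg, j51$output_id[1], "echo ok > {outdir}/r.txt")
  run_local(fx$reg, j53$output_id[1], "echo ok > {outdir}/r.txt")

  tr <- trace(fx$reg, j51$output_id[1])
  expect_identical(nrow(tr), 3L)  # collection <- image <- archive
  expect_identical(tr$kind, c("outputCollection", "image", "dicomArchive"))
  expect_identical(tr$activity_name[1], "freesurfer")
  expect_identical(tr$version[1], "5.1")
  expect_identical(tr$parameters[1], "-all")
  expect_identical(tr$activity_name[3], "upload")
  expect_identical(tr$parent_id[1], img)

  tr53 <- trace(fx$reg, j53$output_id[1])
  expect_identical(tr53$version[1], "5.3")
  # the two chains share their suffix (image <- archive)
  expect_identical(tr[-1, c("id", "kind", "parent_id")],
                   tr53[-1, c("id", "kind", "parent_id")])

  # an uploaded archive is a chain of length 1 with upload provenance
  arch <- trace(fx$reg, fx$batch$archive_id[1])
  expect_identical(nrow(arch), 1L)
  expect_identical(arch$activity_name, "upload")
  expect_true(is.na(arch$parent_id))

  expect_error(trace(fx$reg, "00000000-0000-0000-0000-000000000000"), "unknown asset")
})

test_that("every registered non-upload asset traces to an upload event", {
  fx <- activity_fixture(seed = 13)
  instance_create(fx$reg, "tool", "2.0", "", fx$res$name, "synth")
  jobs <- request_jobs(fx$reg, "tool", "2.0", "", fx$images$id)
  for (oid in jobs$output_id) run_local(fx$reg, oid, "echo x > {outdir}/out.txt")

  assets <- list_assets(fx$reg)
  for (id in assets$id) {
    tr <- trace(fx$reg, id)
    expect_identical(tr$activity_name[nrow(tr)], "upload")
    expect_true(all(diff(tr$depth) >= 0))
  }
})

test_that("an empty ledger gives an all-zero summary", {
  reg <- registry_open(); withr::defer(registry_close(reg))
  summ <- accounting_summary(reg)
  expect_identical(sum(summ$n), 0L)
  expect_setequal(summ$state, c("pending", "staged", "running", "completed", "failed"))
})
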