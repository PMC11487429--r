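test_that("configuration-name grammar round-trips", {
  c1 <- parse_config_name("CS3_L10_CTR75")
  expect_equal(c1[c("cross_section", "length", "ctr", "pitch", "level")],
               list(cross_section = 3, length = 10, ctr = 75, pitch = 3,
                    level = "crystal"))
  c2 <- parse_config_name("CS1.5_L10_CTR75_pitch2")
  expect_equal(c2$pitch, 2)
  c3 <- parse_config_name("CS3_L10_CTR75submod")
  expect_equal(c3$level, "submodule")
  for (nm in c("CS3_L10_CTR75", "CS1.5_L10_CTR75_pitch2", "CS3_L10_CTR75submod",
               "CS2.5_L10_CTR100", "CS3_L7.5_CTR150", "reference"))
    expect_identical(format_config_name(parse_config_name(nm)), nm)
  expect_error(parse_config_name("CS3-L10"), "malformed")
  expect_error(parse_config_name("CS3_L10_CTR75_foo7"), "malformed")
})

test_that("build_scanner wires geometry and policy together", {
  sc <- build_scanner("CS2_L5_CTR150submod")
  expect_equal(sc$geometry$crystal$cross_section, 2)
  expect_equal(sc$geometry$crystal$length, 5)
  expect_equal(sc$policy$ctr_ps, 150)
  expect_equal(sc$policy$level, "submodule")
  ref <- build_scanner("reference")
  expect_equal(ref$geometry$type, "ring")
  expect_equal(ref$policy$window_ns, 4.7)
  expect_equal(ref$policy$energy_policy, "centroid")
})

test_that("relative volume table reproduces the design-summary column", {
  tab <- relative_volume_table()
  expect_equal(tab$relative_volume_pct[tab$name == "reference"], 100)
  want <- c("CS3_L10_CTR75" = 28.9, "CS2.5_L10_CTR75" = 20.1,
            "CS2_L10_CTR75" = 12.8, "CS1.5_L10_CTR75_pitch2" = 16.3,
            "CS3_L7.5_CTR75" = 21.7, "CS3_L5_CTR75" = 14.5)
  for (nm in names(want))
    expect_equal(tab$relative_volume_pct[tab$name == nm], want[[nm]],
                 tolerance = 0.005)
})

test_that("run_study is deterministic under a fixed seed (sensitivity kind)", {
  r1 <- run_study("sensitivity", scanner = "CS3_L10_CTR75", seed = 99,
                  scale = 0.05, step_mm = 150)
  r2 <- run_study("sensitivity", scanner = "CS3_L10_CTR75", seed = 99,
                  scale = 0.05, step_mm = 150)
  expect_identical(r1, r2)
  expect_equal(r1$z_mm, c(-150, 0, 150))
  expect_true(all(r1$sensitivity_kcps_MBq >= 0))
})

test_that("run_study writes tables and provenance", {
  out <- file.path(tempdir(), "pp_study")
  run_study("sensitivity", scanner = "CS3_L10_CTR75", seed = 7, scale = 0.05,
            out_dir = out, step_mm = 300)
  expect_true(file.exists(file.path(out, "sensitivity_CS3_L10_CTR75.csv")))
  prov <- jsonlite::read_json(file.path(out,
                                        "sensitivity_CS3_L10_CTR75_provenance.json"))
  expect_equal(prov$seed, 7)
  expect_equal(prov$scanner, "CS3_L10_CTR75")
  unlink(out, recursive = TRUE)
})

test_that("table1 aggregates analytic and simulated columns", {
  set.seed(77)
  tab <- table1(c("reference", "CS3_L10_CTR75"), scale = 0.02)
  expect_equal(tab$name, c("reference", "CS3_L10_CTR75"))
  expect_equal(tab$relative_volume_pct, c(100, 28.9), tolerance = 0.01)
  expect_true(all(tab$sensitivity_kcps_MBq > 0))
  expect_true(all(tab$necr_tof_cps >= 0))
  expect_true(all(is.na(tab$resolution_x_mm)))
})

test_that("image volumes survive a write/read round-trip", {
  g <- image_grid(1.5, c(5, 6, 7), c(-1, 0, 2))
  img <- image_volume(array(runif(210), c(5, 6, 7)), g)
  p <- file.path(tempdir(), "img.f32")
  write_image(img, p)
  back <- read_image(p)
  expect_equal(back$data, img$data, tolerance = 1e-6)
  expect_equal(back$grid$origin, g$origin)
  unlink(c(p, paste0(p, ".json")))
})

test_that("listmode CSV round-trip", {
  co <- data.table::data.table(id1 = 1:3, id2 = 4:6, t1 = c(1, 2, 3),
                               t2 = c(1.1, 2.1, 3.1), dt_ns = rep(-0.1, 3),
                               class = c("true", "random", "true"))
  p <- file.path(tempdir(), "lm.csv")
  write_listmode(co, p)
  back <- read_listmode(p)
  expect_equal(back$id1, co$id1)
  expect_equal(back$dt_ns, co$dt_ns)
  unlink(p)
})
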