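test_that("the idiogram model mirrors the karyotype's relative lengths", {
  k <- karyotype(table1(), input = "pairs")
  model <- build_idiogram(k)
  expect_s3_class(model, "idiogram")
  expect_equal(nrow(model), 15L)
  # the tallest bar is chromosome 3, the longest of the complement
  expect_identical(model$label[which.max(model$rl_total)], "3")
  expect_equal(max(model$rl_total), 10.1, tolerance = 0.01)
  # bars are grouped by Levan class in canonical order
  expect_identical(unique(model$levan_type), c("m", "sm", "st", "t"))
  # arm extents are proportional to mean arm lengths
  expect_equal(model$rl_short / model$rl_total,
               ifelse(model$rl_short == 0, 0,
                      k$per_chromosome$mean_p[match(model$label,
                                                    k$per_chromosome$label)] /
                        k$per_chromosome$mean_total[match(model$label,
                                                          k$per_chromosome$label)]))
})

test_that("telocentric bars have no short-arm segment", {
  k <- karyotype(data.frame(short_arm_um = c(0, 1), long_arm_um = c(3, 2)),
                 input = "pairs")
  model <- build_idiogram(k)
  expect_equal(model$rl_short[model$levan_type == "t"], 0)
})

test_that("identical pairs draw identical bars", {
  k <- karyotype(data.frame(short_arm_um = c(1, 1), long_arm_um = c(2, 2)),
                 input = "pairs")
  model <- build_idiogram(k)
  expect_equal(model$rl_short[1], model$rl_short[2])
  expect_equal(model$rl_long[1], model$rl_long[2])
})

test_that("the rendered SVG is well-formed and scales with relative length", {
  skip_if_not_installed("xml2")
  k <- karyotype(table1(), input = "pairs")
  model <- build_idiogram(k)
  path <- withr::local_tempfile(fileext = ".svg")
  write_idiogram_svg(model, path)
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "svg")
  rects <- xml2::xml_find_all(doc, ".//*[local-name() = 'rect']")
  # background + 15 long arms + 11 nonzero short arms
  expect_equal(length(rects), 27L)
  rects <- rects[-1]  # drop the percent-sized background
  h <- as.numeric(xml2::xml_attr(rects, "height"))
  # tallest/shortest total bar ratio equals the RL ratio within 0.5%
  x <- xml2::xml_attr(rects, "x")
  bar_heights <- tapply(h, x, sum)
  expect_equal(max(bar_heights) / min(bar_heights),
               max(model$rl_total) / min(model$rl_total),
               tolerance = 0.005)
})

test_that("re-rendering the same model is byte-identical", {
  model <- build_idiogram(karyotype(table1(), input = "pairs"))
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  write_idiogram_svg(model, p1)
  write_idiogram_svg(model, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("an empty model cannot be rendered", {
  expect_error(build_idiogram(data.frame()), "missing")
  m <- build_idiogram(karyotype(table1(), input = "pairs"))
  expect_error(write_idiogram_svg(m[0, ], tempfile()), "non-empty")
})

test_that("the asymmetry scatter plots one marked point per species", {
  sc <- asymmetry_scatter(annelid_karyotypes())
  expect_equal(nrow(sc), 10L)
  uu <- sc[sc$species == "Urechis unicinctus", ]
  expect_equal(c(uu$x, uu$y), c(2.51, 2.54))
  expect_identical(uu$marker, "circle")
  # category -> marker is a bijection over the four categories
  map <- unique(sc[, c("category", "marker")])
  expect_equal(nrow(map), 4L)
  expect_equal(length(unique(map$marker)), 4L)
})

test_that("species missing an axis value are skipped with a warning", {
  tab <- annelid_karyotypes()
  tab$ls_ratio[2] <- NA
  expect_warning(sc <- asymmetry_scatter(tab), "skipping 1 species")
  expect_equal(nrow(sc), 9L)
  one <- asymmetry_scatter(tab[1, ])
  expect_equal(nrow(one), 1L)
  expect_error(asymmetry_scatter(tab[0, ]), "no species")
})

test_that("scatter SVG and CSV outputs are written deterministically", {
  svg1 <- withr::local_tempfile(fileext = ".svg")
  svg2 <- withr::local_tempfile(fileext = ".svg")
  csv <- withr::local_tempfile(fileext = ".csv")
  asymmetry_scatter(annelid_karyotypes(), svg = svg1, csv = csv)
  asymmetry_scatter(annelid_karyotypes(), svg = svg2)
  expect_identical(readLines(svg1), readLines(svg2))
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("species", "category", "ls_ratio", "mean_ar", "marker")
                  %in% names(tab)))
})
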