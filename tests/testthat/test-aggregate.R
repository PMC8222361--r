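test_that("peak map equals max over cases with earliest-regime ties", {
  syn <- synthetic_fields()
  tab <- peak_strain_map(syn$fields, syn$mesh)
  orc <- peak_oracle(syn$fields, syn$mesh)
  expect_equal(tab$peak_vm, orc$peak_vm)
  expect_identical(tab$argmax_index, orc$argmax_index)
  expect_equal(tab$peak_e1, orc$peak_e1)
  expect_equal(tab$peak_e3, orc$peak_e3)
  # single field: the table is that field
  tab1 <- peak_strain_map(syn$fields[1], syn$mesh)
  expect_equal(tab1$peak_vm, syn$fields[[1]]$vm)
  expect_true(all(tab1$argmax_index == 1L))
  # shuffling case order leaves the peaks unchanged
  perm <- c(3, 1, 4, 2)
  tab_s <- peak_strain_map(syn$fields[perm], syn$mesh)
  expect_equal(tab_s$peak_vm, tab$peak_vm)
  expect_error(peak_strain_map(list(), syn$mesh), "at least one")
})

test_that("hand-checked peak selection on a single element", {
  m <- tet_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                matrix(1:4, 1), "bone")
  mk <- function(vm) structure(list(tensor = matrix(0, 1, 6),
                                    principal = matrix(c(vm, 0, -vm), 1),
                                    vm = vm, regime_id = NULL),
                               class = "strain_field")
  tab <- peak_strain_map(lapply(c(10, 50, 30), mk), m)
  expect_equal(tab$peak_vm, 50)
  expect_identical(tab$argmax_index, 2L)
})

test_that("peak aggregation is idempotent and monotone in added regimes", {
  syn <- synthetic_fields()
  tab <- peak_strain_map(syn$fields, syn$mesh)
  # aggregating the peak table with itself returns itself
  peak_field <- structure(list(tensor = matrix(0, nrow(syn$mesh$elems), 6),
                               principal = cbind(tab$peak_e1, 0, tab$peak_e3),
                               vm = tab$peak_vm, regime_id = "peak"),
                          class = "strain_field")
  again <- peak_strain_map(list(peak_field, peak_field), syn$mesh)
  expect_equal(again$peak_vm, tab$peak_vm)
  expect_equal(again$peak_e1, tab$peak_e1)
  expect_equal(again$peak_e3, tab$peak_e3)
  # adding a regime never decreases any element's peak
  for (k in 2:length(syn$fields)) {
    t_k <- peak_strain_map(syn$fields[seq_len(k)], syn$mesh)
    t_km1 <- peak_strain_map(syn$fields[seq_len(k - 1)], syn$mesh)
    expect_true(all(t_k$peak_vm >= t_km1$peak_vm))
  }
})

test_that("bite-mode dominance fractions are volume-weighted and sum to 1", {
  syn <- synthetic_fields()
  tab <- peak_strain_map(syn$fields, syn$mesh)
  modes <- c(case1 = "incisor", case2 = "molar", case3 = "molar",
             case4 = "incisor")
  dom <- dominant_bite_mode(tab, modes)
  expect_equal(sum(dom$volume_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(dom$count_fraction), 1, tolerance = 1e-12)
  # brute-force volume bookkeeping
  cls <- modes[tab$argmax_regime]
  expect_equal(unname(dom$volume_fraction["molar"]),
               sum(tab$volume[cls == "molar"]) / sum(tab$volume))
  # all regimes the same mode: 100%
  allm <- dominant_bite_mode(tab, setNames(rep("molar", 4), names(modes)))
  expect_equal(unname(allm$volume_fraction["molar"]), 1)
  # two equal-volume elements, one incisor-dominant: 50/50
  m2 <- make_unit_cube_mesh(1)
  mk <- function(vm) structure(list(tensor = NULL,
                                    principal = matrix(0, nrow(m2$elems), 3),
                                    vm = vm, regime_id = NULL),
                               class = "strain_field")
  ne <- nrow(m2$elems)
  f1 <- mk(rep(1, ne)); f2 <- mk(rep(1, ne))
  f2$vm[1] <- 2 # regime 2 wins only element 1
  t2 <- peak_strain_map(list(f1, f2), m2)
  d2 <- dominant_bite_mode(t2, c("1" = "incisor", "2" = "molar"))
  v <- element_volumes(m2)
  expect_equal(unname(d2$volume_fraction["molar"]), v[1] / sum(v))
})

test_that("principal dominance classifies by signed peak magnitude with a
           tensile tie rule", {
  tab <- data.frame(element = 1:3, volume = c(1, 1, 2),
                    peak_vm = c(10, 10, 10), argmax_regime = "a",
                    argmax_index = 1L,
                    peak_e1 = c(500, 500, 300), peak_e3 = c(-800, -500, -100))
  dom <- dominant_principal(tab)
  expect_identical(dom$class, c("compressive", "tensile", "tensile"))
  expect_equal(sum(dom$volume_fraction), 1)
  expect_equal(unname(dom$volume_fraction["compressive"]), 0.25)
})

test_that("strain histogram uses half-open 20-microstrain bins", {
  h <- strain_histogram(c(5, 25, 25), bin_width = 20)
  expect_equal(h$count[h$lower == 0], 1L)
  expect_equal(h$count[h$lower == 20], 2L)
  expect_error(strain_histogram(numeric(0)), "empty")
  # bin boundary goes to the upper bin (half-open [k w, (k+1) w))
  h2 <- strain_histogram(c(20), bin_width = 20)
  expect_equal(h2$lower, 20)
  # total count conserved under any bin width
  set.seed(9)
  v <- stats::runif(500, 0, 2000)
  for (w in c(7, 20, 113))
    expect_equal(sum(strain_histogram(v, w)$count), 500L)
})

test_that("band volume fraction uses strict bounds", {
  tab <- data.frame(element = 1:4, volume = rep(1, 4),
                    peak_vm = c(500, 100, 1500, 1499.999),
                    argmax_regime = "a", argmax_index = 1L,
                    peak_e1 = 0, peak_e3 = 0)
  # boundary values 100 and 1500 are excluded
  expect_equal(band_volume_fraction(tab), 0.5)
  tab$peak_vm <- rep(500, 4)
  expect_equal(band_volume_fraction(tab), 1)
  # brute-force volume sum on a random table
  set.seed(2)
  tabr <- data.frame(element = 1:50, volume = stats::runif(50, 0.5, 2),
                     peak_vm = stats::runif(50, 0, 2000),
                     argmax_regime = "a", argmax_index = 1L,
                     peak_e1 = 0, peak_e3 = 0)
  sel <- tabr$peak_vm > 100 & tabr$peak_vm < 1500
  expect_equal(band_volume_fraction(tabr),
               sum(tabr$volume[sel]) / sum(tabr$volume))
})

test_that("sensitivity comparison reports per-element deltas and medians", {
  syn <- synthetic_fields()
  tab <- peak_strain_map(syn$fields, syn$mesh)
  # identical tables: all deltas zero (mesh lacks soft tissue -> use the
  # phantom for the near/far split)
  ph <- small_phantom()
  phf <- function(seed) {
    set.seed(seed)
    ne <- nrow(ph$elems)
    structure(list(tensor = NULL, principal = matrix(0, ne, 3),
                   vm = stats::runif(ne, 0, 100), regime_id = "x"),
              class = "strain_field")
  }
  t1 <- peak_strain_map(list(phf(1)), ph)
  cmp0 <- sensitivity_compare(t1, t1, ph)
  expect_true(all(cmp0$delta == 0))
  # one differing element: exactly one nonzero delta
  t2 <- t1
  t2$peak_vm[100] <- t2$peak_vm[100] + 7
  cmp1 <- sensitivity_compare(t1, t2, ph)
  expect_identical(sum(cmp1$delta != 0), 1L)
  expect_equal(max(cmp1$delta), 7)
})
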