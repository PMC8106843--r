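test_that("aggregation to regions sums counts exactly and preserves grouping", {
  units <- tibble::tibble(
    unit_id = c("z1", "z2", "z3"),
    api_count = c(10, 40, 7), white_count = c(30, 20, 11),
    total_pop = c(100, 100, 50)
  )
  xw <- tibble::tibble(unit_id = c("z1", "z2", "z3"), region_id = c("A", "A", "B"))
  out <- aggregate_to_region(units, xw)

  expect_equal(out$api_total[out$region_id == "A"], 50)

  # independent group-by oracle
  by_hand <- tapply(units$api_count, xw$region_id[match(units$unit_id, xw$unit_id)], sum)
  expect_equal(out$api_total, unname(as.vector(by_hand[out$region_id])))
  expect_equal(out$n_units, c(2L, 1L))
  expect_equal(sum(out$pop_total), sum(units$total_pop))
})

test_that("aggregation handles empty input and rejects bad mappings", {
  empty <- tibble::tibble(
    unit_id = character(), api_count = numeric(),
    white_count = numeric(), total_pop = numeric()
  )
  xw <- tibble::tibble(unit_id = "z1", region_id = "A")
  expect_equal(nrow(aggregate_to_region(empty, xw)), 0)

  units <- tibble::tibble(
    unit_id = "zz9", api_count = 1, white_count = 1, total_pop = 10
  )
  expect_error(aggregate_to_region(units, xw), "zz9")
  dup <- dplyr::bind_rows(units, units)
  xw2 <- tibble::tibble(unit_id = "zz9", region_id = "A")
  expect_error(aggregate_to_region(dup, xw2), "duplicate")
  neg <- dplyr::mutate(units, api_count = -1)
  expect_error(aggregate_to_region(neg, xw2), "negative")
})

test_that("api density matches the closed form and its stated range", {
  expect_equal(api_density(25, 100), 25)
  expect_equal(api_density(120, 120), 100) # all residents API
  expect_equal(api_density(10 + 40, 100 + 100), 25) # 50/200 * 100
  expect_error(api_density(0, 0), "empty region")
})

test_that("dissimilarity matches hand-computed two-unit examples", {
  expect_equal(dissimilarity_index(api_count = c(0, 100), white_count = c(100, 0)), 1)
  expect_equal(dissimilarity_index(api_count = c(50, 50), white_count = c(50, 50)), 0)
  # 0.5 * (|0.8 - 0.2| + |0.2 - 0.8|)
  expect_equal(dissimilarity_index(api_count = c(20, 80), white_count = c(80, 20)), 0.6)
  expect_error(dissimilarity_index(c(0, 0), c(10, 10)), "empty group")
})

test_that("isolation matches hand-computed examples in both variants", {
  expect_equal(isolation_index(api_count = 20, total_pop = 100), 0.2)
  expect_equal(isolation_index(api_count = c(50, 70), total_pop = c(50, 70)), 1)
  # (0.2)(0.2) + (0.8)(0.8)
  expect_equal(isolation_index(api_count = c(20, 80), total_pop = c(100, 100)), 0.68)
  # printed-form variant divides by the region total instead
  expect_equal(
    isolation_index(c(20, 80), c(100, 100), strict_printed_form = TRUE),
    (20 / 100) * (20 / 200) + (80 / 100) * (80 / 200)
  )
  expect_error(isolation_index(c(0, 0), c(10, 10)), "empty group")
  expect_error(isolation_index(c(5, 1), c(10, 0)), "total_pop = 0")
})

test_that("index properties hold over randomized regions", {
  set.seed(101)
  for (i in 1:200) {
    r <- random_region()
    if (sum(r$api) == 0 || sum(r$white) == 0) next
    d <- dissimilarity_index(r$api, r$white)
    iso <- isolation_index(r$api, r$pop)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(iso, 0); expect_lte(iso, 1)
    # isolation is bounded below by the regional API share (Cauchy-Schwarz)
    expect_gte(iso, sum(r$api) / sum(r$pop) - 1e-12)
    # scale invariance
    k <- sample(2:7, 1)
    expect_equal(dissimilarity_index(k * r$api, k * r$white), d)
    expect_equal(isolation_index(k * r$api, k * r$pop), iso)
    expect_equal(
      api_density(sum(k * r$api), sum(k * r$pop)),
      api_density(sum(r$api), sum(r$pop))
    )
    # order invariance and proportional-split invariance for dissimilarity
    perm <- sample(length(r$api))
    expect_equal(dissimilarity_index(r$api[perm], r$white[perm]), d)
    expect_equal(
      dissimilarity_index(
        c(r$api[1] / 2, r$api[1] / 2, r$api[-1]),
        c(r$white[1] / 2, r$white[1] / 2, r$white[-1])
      ),
      d
    )
  }
})

test_that("region_profiles combines the three measures with poverty", {
  units <- tibble::tibble(
    unit_id = c("z1", "z2"), api_count = c(20, 80),
    white_count = c(80, 20), total_pop = c(100, 100)
  )
  xw <- tibble::tibble(unit_id = c("z1", "z2"), region_id = "A")
  pov <- tibble::tibble(region_id = "A", poverty_rate = 0.12)
  prof <- region_profiles(units, xw, pov)
  expect_equal(prof$api_density, 50)
  expect_equal(prof$dissimilarity, 0.6)
  expect_equal(prof$isolation, 0.68)
  expect_equal(prof$poverty_rate, 0.12)
})
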