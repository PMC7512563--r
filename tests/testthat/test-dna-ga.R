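specs3 <- function(l = 8L) list(
  param_spec("q", 1e-3, 2, l),
  param_spec("C", 50, 200, l),
  param_spec("sigma", 0.5, 2, l)
)

test_that("random chromosomes have the right length, alphabet and digit frequencies", {
  rng <- rng_stream(1)
  ch <- random_chromosome(specs3(), rng)
  expect_equal(nchar(ch), 24)
  expect_false(grepl("[^0-3]", ch))
  # determinism under a fixed seed
  expect_identical(random_chromosome(specs3(), rng_stream(42)),
                   random_chromosome(specs3(), rng_stream(42)))
  # single-digit gene: each digit frequency 0.25 +/- 0.02 over 10,000 draws
  rng <- rng_stream(7)
  one <- list(param_spec("x", 0, 1, 1L))
  draws <- vapply(1:10000, function(i) random_chromosome(one, rng), character(1))
  freq <- table(factor(draws, levels = c("0", "1", "2", "3"))) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("decoding maps genes affinely onto the intervals; encoding round-trips", {
  expect_equal(decode_chromosome("00000000", list(param_spec("C", 50, 200)))[["C"]], 50)
  expect_equal(decode_chromosome("33333333", list(param_spec("s", 0.5, 2)))[["s"]], 2)
  expect_equal(decode_chromosome("20000000", list(param_spec("q", 0, 2)))[["q"]],
               2 * 32768 / 65535, tolerance = 1e-12)
  expect_error(decode_chromosome("012", specs3()), "length")

  sp <- specs3()
  expect_identical(encode_chromosome(c(1e-3, 50, 0.5), sp),
                   strrep("0", 24))
  expect_identical(encode_chromosome(c(2, 200, 2), sp), strrep("3", 24))
  expect_error(encode_chromosome(c(5, 50, 0.5), sp), "outside")
  # quantization bound: round-trip error <= half a step
  set.seed(23)
  for (i in 1:100) {
    v <- c(runif(1, 1e-3, 2), runif(1, 50, 200), runif(1, 0.5, 2))
    back <- decode_chromosome(encode_chromosome(v, sp), sp)
    steps <- c(2 - 1e-3, 150, 1.5) / (4^8 - 1)
    expect_true(all(abs(back - v) <= steps / 2 + 1e-12))
  }
  # decode never leaves the interval: exhaustive at l = 4
  sp1 <- list(param_spec("x", -1, 3, 4L))
  digits <- c("0", "1", "2", "3")
  all_genes <- apply(expand.grid(digits, digits, digits, digits), 1, paste,
                     collapse = "")
  vals <- vapply(all_genes, function(g) decode_chromosome(g, sp1)[["x"]],
                 numeric(1))
  expect_true(all(vals >= -1 & vals <= 3))
  expect_equal(sort(unique(vals)), seq(-1, 3, length.out = 256), tolerance = 1e-12)
})

test_that("elitist tournament keeps the best and wins in the enumerated proportion", {
  rng <- rng_stream(2)
  pop <- c("00", "11", "22")
  out <- ga_select(pop, c(0, 1, 0), rng)
  expect_identical(out[1], "11")
  expect_true("11" %in% out)
  # all-equal fitness: a resample of the input multiset
  out2 <- ga_select(pop, c(0.5, 0.5, 0.5), rng)
  expect_true(all(out2 %in% pop))
  expect_error(ga_select(character(0), numeric(0), rng), "empty")
  # binary tournament of fitness (0.9, 0.1): the better individual wins the
  # 3 of 4 equiprobable pairings that include it
  rng <- rng_stream(3)
  wins <- 0; n <- 10000
  for (i in 1:n) {
    s <- ga_select(c("A", "B"), c(0.9, 0.1), rng)
    wins <- wins + (s[2] == "A")
  }
  expect_lt(abs(wins / n - 0.75), 0.02)
})

test_that("crossover operators reproduce the printed segment patterns", {
  ch <- "0011223301"  # segments 00|11|22|33|01, positions 1..5 left to right
  expect_identical(crossover_transformation(ch, 2, 4), "0033221101")
  expect_identical(crossover_transformation(ch, 3, 3), ch)
  expect_identical(crossover_transformation(crossover_transformation(ch, 2, 4), 2, 4), ch)

  expect_identical(crossover_permutation(ch, "12", 4), "0011221201")
  expect_identical(crossover_permutation(ch, "33", 4), ch)
  expect_error(crossover_permutation(ch, "123", 4), "length")

  expect_identical(crossover_translocation(ch, 4, 2), "0033112201")
  expect_identical(crossover_translocation(ch, 4, 4), ch)
  # digit multiset is conserved by any translocation
  set.seed(31)
  for (i in 1:20) {
    from <- sample(5, 1); to <- sample(5, 1)
    moved <- crossover_translocation(ch, from, to)
    expect_identical(sort(strsplit(moved, "")[[1]]), sort(strsplit(ch, "")[[1]]))
  }
  # donor from a second parent: all output digits come from the two parents
  p2 <- "3322110033"
  donor <- substr(p2, 7, 8)
  child <- crossover_permutation(ch, donor, 4)
  expect_false(grepl("[^0-3]", child))
  expect_equal(nchar(child), nchar(ch))
})

test_that("mutation maps match the substitution tables and their algebra", {
  expect_identical(mutate_reversal("0123", 1:4), "2301")
  expect_identical(mutate_transition("0123", 1:4), "1032")
  expect_identical(mutate_exchange("0123", 1:4), "3210")
  # involutions, fixed-point-free, reversal o transition = exchange
  for (d in c("0", "1", "2", "3")) {
    expect_identical(mutate_reversal(mutate_reversal(d, 1), 1), d)
    expect_identical(mutate_transition(mutate_transition(d, 1), 1), d)
    expect_identical(mutate_exchange(mutate_exchange(d, 1), 1), d)
    expect_false(mutate_reversal(d, 1) == d)
    expect_false(mutate_transition(d, 1) == d)
    expect_false(mutate_exchange(d, 1) == d)
    expect_identical(mutate_transition(mutate_reversal(d, 1), 1),
                     mutate_exchange(d, 1))
  }
  # point mutation: exactly one position changes, to a different digit
  rng <- rng_stream(5)
  ch <- "0123012301230123"
  for (i in 1:50) {
    pos <- sample(nchar(ch), 1)
    mut <- mutate_point(ch, pos, rng)
    diff <- which(strsplit(mut, "")[[1]] != strsplit(ch, "")[[1]])
    expect_identical(diff, pos)
  }
  expect_identical(mutate_point("0123", 2, rng_stream(9)),
                   mutate_point("0123", 2, rng_stream(9)))
  # replacement digit approximately uniform over the three alternatives
  rng <- rng_stream(6)
  res <- vapply(1:9999, function(i) substr(mutate_point("0", 1, rng), 1, 1),
                character(1))
  freq <- table(factor(res, levels = c("1", "2", "3"))) / 9999
  expect_true(all(abs(freq - 1 / 3) < 0.02))
})

test_that("all operators preserve chromosome length and alphabet under random use", {
  rng <- rng_stream(8)
  sp <- specs3()
  ch <- random_chromosome(sp, rng)
  for (i in 1:2000) {
    op <- sample(7, 1)
    ch2 <- switch(op,
      crossover_transformation(ch, sample(5, 1), sample(5, 1)),
      crossover_permutation(ch, substr(ch, 1, 5), 1),  # segment 1 spans digits 1..5 at L = 24
      crossover_translocation(ch, sample(5, 1), sample(5, 1)),
      mutate_reversal(ch, sample(nchar(ch), 1)),
      mutate_transition(ch, sample(nchar(ch), 1)),
      mutate_exchange(ch, sample(nchar(ch), 1)),
      mutate_point(ch, sample(nchar(ch), 1), rng))
    expect_equal(nchar(ch2), 24)
    expect_false(grepl("[^0-3]", ch2))
    ch <- ch2
  }
})

test_that("evolution maximizes simple objectives and its trajectory is monotone", {
  # maximizing the decoded value drives it to the upper bound
  sp <- list(param_spec("q", 0, 2))
  r <- dnaga_evolve(function(ch) decode_chromosome(ch, sp)[["q"]] / 2, sp,
                    ga_config(pop_size = 20, max_generations = 30, seed = 1))
  expect_gte(r$best_values[["q"]], 1.99)
  expect_true(all(diff(r$history$best) >= 0))

  # Gmax = 1: the best of the initial random population, untouched
  rng_init <- rng_stream(ga_config(seed = 4)$seed)
  init <- vapply(1:10, function(i) random_chromosome(sp, rng_init), character(1))
  f <- function(ch) decode_chromosome(ch, sp)[["q"]] / 2
  r1 <- dnaga_evolve(f, sp, ga_config(pop_size = 10, max_generations = 1, seed = 4))
  expect_identical(r1$best_chromosome, init[which.max(vapply(init, f, numeric(1)))])
  expect_equal(nrow(r1$history), 1)

  # determinism: identical runs under the same seed
  ra <- dnaga_evolve(f, sp, ga_config(pop_size = 15, max_generations = 10, seed = 2))
  rb <- dnaga_evolve(f, sp, ga_config(pop_size = 15, max_generations = 10, seed = 2))
  expect_identical(ra$history, rb$history)
  expect_identical(ra$best_chromosome, rb$best_chromosome)

  # non-finite fitness is rejected
  expect_error(
    dnaga_evolve(function(ch) NaN, sp, ga_config(pop_size = 4, max_generations = 2, seed = 1)),
    "non-finite")
})
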