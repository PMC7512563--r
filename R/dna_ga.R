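# DNA genetic algorithm over quaternary chromosomes.
#
# Individuals are strings over {0,1,2,3}, read as nucleotide bases with the
# fixed map C=0, T=1, A=2, G=3 (the unique assignment consistent with the
# three base-substitution mutation tables below). A chromosome concatenates
# one fixed-length gene per tuned parameter; decoding reads each gene as a
# big-endian base-4 integer mapped affinely onto the parameter's interval.

#' Define a tuned parameter's search interval and gene length
#'
#' @param name parameter name.
#' @param lower,upper interval bounds, \code{lower < upper}.
#' @param gene_length digits of the base-4 gene (default 8, resolution
#'   \code{(upper - lower)/65535}).
#' @return a \code{param_spec} object.
#' @export
param_spec <- function(name, lower, upper, gene_length = 8L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lower), is.numeric(upper), lower < upper,
            gene_length >= 1L)
  structure(list(name = name, lower = lower, upper = upper,
                 gene_length = as.integer(gene_length)),
            class = "param_spec")
}

#' Default search intervals for (q, C, sigma)
#'
#' The \code{"aanlib"} preset uses q in (0, 1), C in (50, 200), sigma in
#' \[0.5, 2\]; the \code{"sbd"} preset widens q to (0, 2).
#'
#' @param preset \code{"aanlib"} or \code{"sbd"}.
#' @param gene_length digits per gene.
#' @return list of three \code{param_spec}s named q, C, sigma.
#' @export
default_param_specs <- function(preset = c("aanlib", "sbd"), gene_length = 8L) {
  preset <- match.arg(preset)
  q_upper <- if (preset == "sbd") 2 else 1
  list(
    param_spec("q", 1e-3, q_upper, gene_length),
    param_spec("C", 50, 200, gene_length),
    param_spec("sigma", 0.5, 2, gene_length)
  )
}

.total_length <- function(specs) sum(vapply(specs, `[[`, integer(1), "gene_length"))

.check_chrom <- function(digits) {
  if (!is.character(digits) || length(digits) != 1L ||
      grepl("[^0-3]", digits)) {
    stop("chromosome must be a string over {0,1,2,3}", call. = FALSE)
  }
  invisible(digits)
}

#' Draw a random chromosome
#'
#' @param specs list of \code{param_spec}s.
#' @param rng an \code{rng_stream}.
#' @return digit string of length equal to the summed gene lengths.
#' @export
random_chromosome <- function(specs, rng) {
  stopifnot(length(specs) >= 1L)
  L <- .total_length(specs)
  paste(with_rng(rng, sample(0:3, L, replace = TRUE)), collapse = "")
}

#' Decode a chromosome into parameter values
#'
#' Each gene is read big-endian as an integer \code{v} in
#' \code{[0, 4^l - 1]} and mapped to
#' \code{lower + v / (4^l - 1) * (upper - lower)}; decoded values therefore
#' never leave the search interval.
#'
#' @param chrom digit string.
#' @param specs list of \code{param_spec}s.
#' @return named numeric vector of parameter values.
#' @export
decode_chromosome <- function(chrom, specs) {
  .check_chrom(chrom)
  L <- .total_length(specs)
  if (nchar(chrom) != L) stop("chromosome length mismatch", call. = FALSE)
  d <- as.integer(strsplit(chrom, "")[[1]])
  out <- numeric(length(specs))
  names(out) <- vapply(specs, `[[`, character(1), "name")
  pos <- 1L
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    g <- d[pos:(pos + s$gene_length - 1L)]
    v <- sum(g * 4^((s$gene_length - 1L):0))
    out[i] <- s$lower + v / (4^s$gene_length - 1) * (s$upper - s$lower)
    pos <- pos + s$gene_length
  }
  out
}

#' Encode parameter values as a chromosome
#'
#' Nearest-integer quantization; \code{decode_chromosome(encode_chromosome(v))}
#' deviates from \code{v} by at most half a quantization step per parameter.
#'
#' @param values numeric vector, one value per spec, inside the intervals.
#' @param specs list of \code{param_spec}s.
#' @return digit string.
#' @export
encode_chromosome <- function(values, specs) {
  stopifnot(length(values) == length(specs))
  genes <- character(length(specs))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (values[i] < s$lower || values[i] > s$upper) {
      stop(sprintf("value %g outside [%g, %g] for '%s'",
                   values[i], s$lower, s$upper, s$name), call. = FALSE)
    }
    v <- round((values[i] - s$lower) / (s$upper - s$lower) *
                 (4^s$gene_length - 1))
    d <- integer(s$gene_length)
    for (k in s$gene_length:1) {
      d[k] <- v %% 4
      v <- v %/% 4
    }
    genes[i] <- paste(d, collapse = "")
  }
  paste(genes, collapse = "")
}

# ---- selection ----

#' Elitist binary tournament selection
#'
#' Fills \code{length(fitness)} slots by binary tournaments with
#' replacement; the best parent is always copied into slot 1 (elitism).
#'
#' @param population character vector of chromosomes.
#' @param fitness numeric vector of fitness values.
#' @param rng an \code{rng_stream}.
#' @return character vector of selected chromosomes, same length.
#' @export
ga_select <- function(population, fitness, rng) {
  n <- length(population)
  if (n == 0L) stop("empty population", call. = FALSE)
  stopifnot(length(fitness) == n, all(is.finite(fitness)))
  best <- which.max(fitness)
  out <- character(n)
  out[1] <- population[best]
  if (n > 1L) {
    idx <- with_rng(rng, matrix(sample.int(n, 2L * (n - 1L), replace = TRUE),
                                ncol = 2L))
    winner <- ifelse(fitness[idx[, 1]] >= fitness[idx[, 2]],
                     idx[, 1], idx[, 2])
    out[2:n] <- population[winner]
  }
  out
}

# ---- crossover ----

# near-equal split into n_seg contiguous segments, remainder to the leftmost
.segment_bounds <- function(L, n_seg = 5L) {
  if (L < n_seg) stop("chromosome too short for segmentation", call. = FALSE)
  base <- L %/% n_seg
  sizes <- rep.int(base, n_seg)
  extra <- L %% n_seg
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

.split_segments <- function(chrom, n_seg = 5L) {
  b <- .segment_bounds(nchar(chrom), n_seg)
  vapply(seq_len(nrow(b)), function(i) substr(chrom, b[i, 1], b[i, 2]),
         character(1))
}

#' Transformation crossover: two segments exchange positions
#'
#' The chromosome is split into 5 contiguous near-equal segments (positions
#' numbered 1..5 left to right); segments \code{seg_i} and \code{seg_j} swap
#' places.
#'
#' @param chrom digit string.
#' @param seg_i,seg_j segment positions in 1..5, distinct.
#' @return the recombined chromosome.
#' @export
crossover_transformation <- function(chrom, seg_i, seg_j) {
  .check_chrom(chrom)
  segs <- .split_segments(chrom)
  if (!seg_i %in% seq_along(segs) || !seg_j %in% seq_along(segs)) {
    stop("invalid segment index", call. = FALSE)
  }
  tmp <- segs[seg_i]; segs[seg_i] <- segs[seg_j]; segs[seg_j] <- tmp
  paste(segs, collapse = "")
}

#' Permutation crossover: a donor segment replaces one segment
#'
#' @param chrom digit string.
#' @param donor_segment replacement digits, same length as the target
#'   segment (typically the corresponding segment of another individual).
#' @param seg_idx target segment position in 1..5.
#' @return the recombined chromosome.
#' @export
crossover_permutation <- function(chrom, donor_segment, seg_idx) {
  .check_chrom(chrom)
  .check_chrom(donor_segment)
  segs <- .split_segments(chrom)
  if (!seg_idx %in% seq_along(segs)) stop("invalid segment index", call. = FALSE)
  if (nchar(donor_segment) != nchar(segs[seg_idx])) {
    stop("donor segment length mismatch", call. = FALSE)
  }
  segs[seg_idx] <- donor_segment
  paste(segs, collapse = "")
}

#' Translocation crossover: a segment moves to a new position
#'
#' The segment at \code{seg_idx} is removed and reinserted so that it ends
#' up at position \code{dest} of the resulting segment sequence; the digit
#' multiset is preserved.
#'
#' @param chrom digit string.
#' @param seg_idx segment position in 1..5 to move.
#' @param dest destination position in 1..5.
#' @return the rearranged chromosome.
#' @export
crossover_translocation <- function(chrom, seg_idx, dest) {
  .check_chrom(chrom)
  segs <- .split_segments(chrom)
  n <- length(segs)
  if (!seg_idx %in% seq_len(n) || !dest %in% seq_len(n)) {
    stop("invalid segment index", call. = FALSE)
  }
  ord <- append(setdiff(seq_len(n), seg_idx), seg_idx, after = dest - 1L)
  paste(segs[ord], collapse = "")
}

# ---- mutation ----

.map_mutate <- function(chrom, pos, map) {
  .check_chrom(chrom)
  d <- strsplit(chrom, "")[[1]]
  if (any(pos < 1L | pos > length(d))) stop("position out of range", call. = FALSE)
  d[pos] <- map[d[pos]]
  paste(d, collapse = "")
}

#' Base-substitution and point mutations
#'
#' Single-digit substitutions at the given position(s):
#' \describe{
#'   \item{reversal}{C<->A, T<->G, i.e. 0<->2, 1<->3}
#'   \item{transition}{C<->T, A<->G, i.e. 0<->1, 2<->3}
#'   \item{exchange}{A<->T, C<->G, i.e. 2<->1, 0<->3}
#'   \item{point}{the digit is replaced by a uniformly chosen different
#'     digit (both transitions and transversions possible)}
#' }
#' Each of the three deterministic maps is a fixed-point-free involution, and
#' reversal composed with transition equals exchange.
#'
#' @param chrom digit string.
#' @param pos integer position(s) in 1..nchar(chrom).
#' @param rng an \code{rng_stream} (point mutation only).
#' @return the mutated chromosome.
#' @name mutations
NULL

#' @rdname mutations
#' @export
mutate_reversal <- function(chrom, pos) {
  .map_mutate(chrom, pos, c(`0` = "2", `1` = "3", `2` = "0", `3` = "1"))
}

#' @rdname mutations
#' @export
mutate_transition <- function(chrom, pos) {
  .map_mutate(chrom, pos, c(`0` = "1", `1` = "0", `2` = "3", `3` = "2"))
}

#' @rdname mutations
#' @export
mutate_exchange <- function(chrom, pos) {
  .map_mutate(chrom, pos, c(`0` = "3", `1` = "2", `2` = "1", `3` = "0"))
}

#' @rdname mutations
#' @export
mutate_point <- function(chrom, pos, rng) {
  .check_chrom(chrom)
  d <- strsplit(chrom, "")[[1]]
  if (any(pos < 1L | pos > length(d))) stop("position out of range", call. = FALSE)
  for (p in pos) {
    alt <- setdiff(c("0", "1", "2", "3"), d[p])
    d[p] <- with_rng(rng, sample(alt, 1L))
  }
  paste(d, collapse = "")
}

# ---- evolution loop ----

#' DNA-GA configuration
#'
#' @param pop_size population ("DNA soup") size T (default 20).
#' @param max_generations generation cap Gmax (default 30).
#' @param p_crossover per-individual crossover probability pc (default 0.8).
#' @param p_mutation per-digit mutation probability pm (default 0.02).
#' @param delta fitness-stall threshold for early stopping (default 1e-4).
#' @param stall_window consecutive generations the best fitness must change
#'   by less than \code{delta} before stopping (default 3; a single-step
#'   rule halts too eagerly under stochastic fitness).
#' @param seed integer seed for the GA stream.
#' @return a \code{ga_config} list.
#' @export
ga_config <- function(pop_size = 20L, max_generations = 30L,
                      p_crossover = 0.8, p_mutation = 0.02,
                      delta = 1e-4, stall_window = 3L, seed = 1L) {
  stopifnot(pop_size >= 1L, max_generations >= 1L,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1, delta > 0)
  structure(list(pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 delta = delta, stall_window = as.integer(stall_window),
                 seed = as.integer(seed)),
            class = "ga_config")
}

.apply_crossover <- function(pop, pc, rng) {
  n <- length(pop)
  if (n < 2L) return(pop)
  new_pop <- pop
  for (i in 2:n) {  # slot 1 holds the elite copy, exempt from variation
    if (with_rng(rng, stats::runif(1)) >= pc) next
    op <- with_rng(rng, sample.int(3L, 1L))
    if (op == 1L) {
      ij <- with_rng(rng, sample.int(5L, 2L))
      new_pop[i] <- crossover_transformation(pop[i], ij[1], ij[2])
    } else if (op == 2L) {
      j <- with_rng(rng, sample(setdiff(seq_len(n), i), 1L))
      seg <- with_rng(rng, sample.int(5L, 1L))
      donor <- .split_segments(pop[j])[seg]
      new_pop[i] <- crossover_permutation(pop[i], donor, seg)
    } else {
      seg <- with_rng(rng, sample.int(5L, 1L))
      dest <- with_rng(rng, sample(setdiff(seq_len(5L), seg), 1L))
      new_pop[i] <- crossover_translocation(pop[i], seg, dest)
    }
  }
  new_pop
}

.apply_mutation <- function(pop, pm, rng) {
  n <- length(pop)
  if (n < 2L || pm <= 0) return(pop)
  for (i in 2:n) {
    L <- nchar(pop[i])
    hit <- which(with_rng(rng, stats::runif(L)) < pm)
    for (p in hit) {
      op <- with_rng(rng, sample.int(4L, 1L))
      pop[i] <- switch(op,
                       mutate_reversal(pop[i], p),
                       mutate_transition(pop[i], p),
                       mutate_exchange(pop[i], p),
                       mutate_point(pop[i], p, rng))
    }
  }
  pop
}

#' Run the DNA genetic algorithm
#'
#' Evolves a population of quaternary chromosomes against a fitness function
#' (values in \[0, 1\], maximized). Each generation applies elitist binary
#' tournament selection, then one uniformly chosen crossover operator per
#' individual with probability \code{p_crossover} (permutation donors drawn
#' from a random other individual), then one uniformly chosen mutation
#' operator per digit with probability \code{p_mutation}; the elite copy in
#' slot 1 is exempt from variation. Evolution stops at
#' \code{max_generations} or when the best fitness changes by less than
#' \code{delta} for \code{stall_window} consecutive generations.
#'
#' @param fitness_fn function(chromosome) -> fitness in \[0, 1\].
#' @param specs list of \code{param_spec}s.
#' @param config a \code{ga_config}.
#' @param rng optional \code{rng_stream}; defaults to one seeded from
#'   \code{config$seed}.
#' @return list with \code{best_chromosome}, \code{best_values} (decoded),
#'   \code{best_fitness}, and \code{history} — a tibble with one row per
#'   generation (generation, best, mean).
#' @export
dnaga_evolve <- function(fitness_fn, specs, config = ga_config(), rng = NULL) {
  stopifnot(inherits(config, "ga_config"))
  if (is.null(rng)) rng <- rng_stream(config$seed)
  memo <- new.env(parent = emptyenv())
  eval_fit <- function(chrom) {
    f <- get0(chrom, envir = memo, inherits = FALSE)
    if (!is.null(f)) return(f)
    f <- fitness_fn(chrom)
    if (!is.finite(f)) stop("fitness function returned a non-finite value",
                            call. = FALSE)
    assign(chrom, f, envir = memo)
    f
  }

  pop <- vapply(seq_len(config$pop_size), function(i) random_chromosome(specs, rng),
                character(1))
  fit <- vapply(pop, eval_fit, numeric(1), USE.NAMES = FALSE)
  best_ever <- pop[which.max(fit)]
  best_ever_fit <- max(fit)
  history <- list(data.frame(generation = 1L, best = best_ever_fit,
                             mean = mean(fit)))
  stall <- 0L
  gen <- 1L
  while (gen < config$max_generations) {
    pop <- ga_select(pop, fit, rng)
    pop <- .apply_crossover(pop, config$p_crossover, rng)
    pop <- .apply_mutation(pop, config$p_mutation, rng)
    fit <- vapply(pop, eval_fit, numeric(1), USE.NAMES = FALSE)
    gen <- gen + 1L
    prev_best <- best_ever_fit
    if (max(fit) > best_ever_fit) {
      best_ever_fit <- max(fit)
      best_ever <- pop[which.max(fit)]
    }
    history[[gen]] <- data.frame(generation = gen, best = best_ever_fit,
                                 mean = mean(fit))
    stall <- if (abs(best_ever_fit - prev_best) < config$delta) stall + 1L else 0L
    if (stall >= config$stall_window) break
  }
  list(best_chromosome = best_ever,
       best_values = decode_chromosome(best_ever, specs),
       best_fitness = best_ever_fit,
       history = tibble::as_tibble(do.call(rbind, history)))
}
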