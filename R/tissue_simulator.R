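#' Simulation configuration for the synthetic tissue generator
#'
#' Describes an in-silico spatial transcriptomics experiment: virtual cells
#' with a single artificial chromosome populate a rectangular tissue domain
#' by stochastic growth. At every step each cell moves, divides, dies or
#' stays stagnant; at division the offspring may acquire a copy-number
#' mutation on one contiguous gene segment (+/- 1 copy, clamped). Cells are
#' then binned into a Visium-like spot grid and UMI counts are drawn with
#' per-gene intensity proportional to copy number.
#'
#' `p_mutation_at_division` may be a scalar or a vector with one probability
#' per step; the default schedule confines mutations to the early expansion
#' phase so that the handful of simulated events found spatially coherent
#' clones (late mutations under pure exponential growth almost surely yield
#' single-cell clones).
#'
#' @param domain_size Width/height of the tissue domain (arbitrary units).
#' @param n_founders Number of founding diploid cells.
#' @param n_steps Number of growth steps.
#' @param p_move,p_divide,p_die,p_stagnate Per-cell per-step action
#'   probabilities; must sum to 1.
#' @param p_mutation_at_division Probability that a division mutates the
#'   offspring; scalar or length-`n_steps` vector.
#' @param n_genes Genes on the single artificial chromosome.
#' @param max_copy_number Copies are clamped to `[0, max_copy_number]`.
#' @param segment_length_distribution `(min_genes, max_genes)` for the
#'   uniformly drawn mutated segment length.
#' @param move_step_max Maximum displacement per move (uniform in a disc),
#'   clipped to the domain.
#' @param division_distance Offspring is placed at this distance from the
#'   parent, in a uniform random direction.
#' @param spot_diameter Capture diameter of a spot; must not exceed the pitch.
#' @param spot_pitch Centre-to-centre spot spacing (square grid).
#' @param baseline_expression Per-gene positive baseline rates (scalar
#'   recycled to `n_genes`).
#' @param mean_spot_depth Expected total UMIs per spot.
#' @param depth_dispersion Negative-binomial size parameter for spot depth.
#' @param seed Integer seed; the same seed reproduces the tissue exactly.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(domain_size = c(1000, 1000),
                              n_founders = 5,
                              n_steps = 33,
                              p_move = 0.05,
                              p_divide = 0.25,
                              p_die = 0.05,
                              p_stagnate = 0.65,
                              p_mutation_at_division = c(rep(0.08, 12), rep(0, 21)),
                              n_genes = 600,
                              max_copy_number = 6,
                              segment_length_distribution = c(60, 150),
                              move_step_max = 5,
                              division_distance = 14,
                              spot_diameter = 11,
                              spot_pitch = 12,
                              baseline_expression = 1,
                              mean_spot_depth = 5000,
                              depth_dispersion = 10,
                              seed = 1L) {
  probs <- c(p_move, p_divide, p_die, p_stagnate)
  if (any(probs < 0) || any(probs > 1)) stop("action probabilities must lie in [0,1]")
  if (abs(sum(probs) - 1) > 1e-8) stop("p_move + p_divide + p_die + p_stagnate must equal 1")
  if (length(p_mutation_at_division) == 1) {
    p_mutation_at_division <- rep(p_mutation_at_division, n_steps)
  }
  if (length(p_mutation_at_division) != n_steps) {
    stop("p_mutation_at_division must be scalar or length n_steps")
  }
  if (any(p_mutation_at_division < 0 | p_mutation_at_division > 1)) {
    stop("mutation probabilities must lie in [0,1]")
  }
  stopifnot(n_genes >= 1, max_copy_number >= 0,
            length(segment_length_distribution) == 2,
            segment_length_distribution[1] >= 1,
            segment_length_distribution[2] >= segment_length_distribution[1])
  baseline_expression <- rep_len(baseline_expression, n_genes)
  if (any(baseline_expression <= 0)) stop("baseline_expression must be positive")
  structure(list(domain_size = domain_size, n_founders = n_founders,
                 n_steps = n_steps, p_move = p_move, p_divide = p_divide,
                 p_die = p_die, p_stagnate = p_stagnate,
                 p_mutation_at_division = p_mutation_at_division,
                 n_genes = n_genes, max_copy_number = max_copy_number,
                 segment_length_distribution = segment_length_distribution,
                 move_step_max = move_step_max,
                 division_distance = division_distance,
                 spot_diameter = spot_diameter, spot_pitch = spot_pitch,
                 baseline_expression = baseline_expression,
                 mean_spot_depth = mean_spot_depth,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation design file (TOML)
#'
#' Minimal TOML subset: `key = value` lines with numbers, strings, booleans
#' and flat arrays; table headers are ignored (keys are flattened). Keys must
#' match [simulation_config()] arguments.
#'
#' @param path TOML file path.
#' @return A `sim_config`.
#' @export
read_simulation_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^\\[", lines)]
  vals <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(kv) != 3) stop("cannot parse TOML line: ", ln)
    vals[[kv[2]]] <- parse_toml_value(trimws(kv[3]))
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) stop("unknown design keys: ", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

parse_toml_value <- function(txt) {
  if (grepl("^\\[", txt)) {
    inner <- sub("^\\[", "", sub("\\]$", "", txt))
    parts <- trimws(strsplit(inner, ",")[[1]])
    parts <- parts[nzchar(parts)]
    return(vapply(parts, function(p) parse_toml_value(p), numeric(1), USE.NAMES = FALSE))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  suppressWarnings(num <- as.numeric(txt))
  if (is.na(num)) stop("cannot parse TOML value: ", txt)
  num
}

#' Simulate tissue growth
#'
#' Runs the agent-based generative process: founders are placed uniformly in
#' the domain and updated for `n_steps`. Moving displaces a cell by a uniform
#' random step of at most `move_step_max`, clipped to the domain; division
#' places the offspring at `division_distance` from the parent (the offspring
#' inherits the parent genome and, with the step's mutation probability, a
#' uniformly chosen contiguous segment gains or loses one copy, clamped to
#' `[0, max_copy_number]`); dying removes the cell. Lineage, genotypes and
#' the mutation event log are recorded. Identical seeds give identical
#' tissues.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_tissue` list: `cells` (data frame id, x, y, parent,
#'   genotype, alive, birth_step), `genotypes` (matrix genotype x gene of
#'   absolute copy numbers; diploid = 2), `events` (mutation log), `config`.
#' @export
simulate_tissue <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  w <- config$domain_size[1]; h <- config$domain_size[2]

  cap <- 4096L
  x <- numeric(cap); y <- numeric(cap)
  parent <- integer(cap); genotype <- integer(cap)
  alive <- logical(cap); birth <- integer(cap)
  n <- config$n_founders
  x[1:n] <- stats::runif(n, 0, w)
  y[1:n] <- stats::runif(n, 0, h)
  parent[1:n] <- NA_integer_
  genotype[1:n] <- 1L
  alive[1:n] <- TRUE
  birth[1:n] <- 0L

  genotypes <- matrix(2L, nrow = 1, ncol = ng)
  geno_key <- new.env(parent = emptyenv())
  assign(paste(genotypes[1, ], collapse = ","), 1L, envir = geno_key)
  events <- list()

  grow <- function(need) {
    while (need > cap) {
      cap <<- cap * 2L
      length(x) <<- cap; length(y) <<- cap
      length(parent) <<- cap; length(genotype) <<- cap
      length(alive) <<- cap; length(birth) <<- cap
    }
  }

  for (step in seq_len(config$n_steps)) {
    idx <- which(alive[1:n])
    if (length(idx) == 0) {
      stop("population went extinct at step ", step - 1L)
    }
    action <- sample(c("move", "divide", "die", "stagnate"), length(idx),
                     replace = TRUE,
                     prob = c(config$p_move, config$p_divide,
                              config$p_die, config$p_stagnate))
    mv <- idx[action == "move"]
    if (length(mv) > 0) {
      r <- config$move_step_max * sqrt(stats::runif(length(mv)))
      th <- stats::runif(length(mv), 0, 2 * pi)
      x[mv] <- pmin(pmax(x[mv] + r * cos(th), 0), w)
      y[mv] <- pmin(pmax(y[mv] + r * sin(th), 0), h)
    }
    dd <- idx[action == "die"]
    if (length(dd) > 0) alive[dd] <- FALSE
    dv <- idx[action == "divide"]
    if (length(dv) > 0) {
      grow(n + length(dv))
      p_mut <- config$p_mutation_at_division[step]
      for (i in dv) {
        n <- n + 1L
        th <- stats::runif(1, 0, 2 * pi)
        x[n] <- min(max(x[i] + config$division_distance * cos(th), 0), w)
        y[n] <- min(max(y[i] + config$division_distance * sin(th), 0), h)
        parent[n] <- i
        birth[n] <- step
        alive[n] <- TRUE
        g <- genotype[i]
        if (stats::runif(1) < p_mut) {
          len <- sample(seq(config$segment_length_distribution[1],
                            min(config$segment_length_distribution[2], ng)), 1)
          start <- sample(ng - len + 1L, 1)
          delta <- sample(c(-1L, 1L), 1)
          cn <- genotypes[g, ]
          seg <- start:(start + len - 1L)
          cn[seg] <- pmin(pmax(cn[seg] + delta, 0L), config$max_copy_number)
          key <- paste(cn, collapse = ",")
          gid <- get0(key, envir = geno_key)
          if (is.null(gid)) {
            genotypes <- rbind(genotypes, cn)
            gid <- nrow(genotypes)
            assign(key, gid, envir = geno_key)
          }
          events[[length(events) + 1L]] <-
            data.frame(step = step, cell = n, seg_start = start,
                       seg_end = start + len - 1L, delta = delta,
                       from_genotype = g, to_genotype = gid)
          g <- gid
        }
        genotype[n] <- g
      }
    }
  }
  if (!any(alive[1:n])) stop("population went extinct at step ", config$n_steps)

  rownames(genotypes) <- NULL
  cells <- data.frame(id = seq_len(n), x = x[1:n], y = y[1:n],
                      parent = parent[1:n], genotype = genotype[1:n],
                      alive = alive[1:n], birth_step = birth[1:n])
  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(step = integer(), cell = integer(), seg_start = integer(),
               seg_end = integer(), delta = integer(),
               from_genotype = integer(), to_genotype = integer())
  structure(list(cells = cells, genotypes = genotypes, events = ev,
                 config = config),
            class = "synthetic_tissue")
}

#' @export
print.synthetic_tissue <- function(x, ...) {
  live <- x$cells[x$cells$alive, ]
  cat(sprintf("synthetic_tissue: %d live cells (%d total), %d genotypes, %d mutation events\n",
              nrow(live), nrow(x$cells), nrow(x$genotypes), nrow(x$events)))
  if (!is.null(x$spots)) {
    cat(sprintf("  binned: %d occupied spots\n", nrow(x$spots)))
  }
  invisible(x)
}

#' Bin cells into a spot grid
#'
#' Lays a square grid of spot centres at `spot_pitch` over the domain and
#' assigns each live cell to the spot whose centre lies within
#' `spot_diameter / 2`; cells in the inter-spot gap stay unassigned. Spots
#' capturing zero cells are dropped.
#'
#' @param tissue A `synthetic_tissue`.
#' @param config Defaults to `tissue$config`.
#' @return The tissue with `spots` (data frame barcode, cx, cy) and
#'   `spot_of_cell` (index into `spots` or `NA`, aligned to `cells`).
#' @export
bin_cells_to_spots <- function(tissue, config = tissue$config) {
  if (config$spot_diameter > config$spot_pitch) {
    stop("spot_diameter exceeds spot_pitch: overlapping capture areas are not modelled")
  }
  pitch <- config$spot_pitch
  cx <- seq(pitch / 2, config$domain_size[1], by = pitch)
  cy <- seq(pitch / 2, config$domain_size[2], by = pitch)
  cells <- tissue$cells
  gi <- pmin(pmax(round((cells$x - pitch / 2) / pitch) + 1, 1), length(cx))
  gj <- pmin(pmax(round((cells$y - pitch / 2) / pitch) + 1, 1), length(cy))
  d2 <- (cells$x - cx[gi])^2 + (cells$y - cy[gj])^2
  ok <- cells$alive & d2 <= (config$spot_diameter / 2)^2
  key <- ifelse(ok, paste0("s", gi, "_", gj), NA)
  occupied <- sort(unique(key[!is.na(key)]))
  spot_of_cell <- match(key, occupied)
  ii <- as.integer(sub("^s(\\d+)_.*", "\\1", occupied))
  jj <- as.integer(sub("^s\\d+_(\\d+)$", "\\1", occupied))
  tissue$spots <- data.frame(barcode = occupied, cx = cx[ii], cy = cy[jj],
                             array_col = ii, array_row = jj,
                             stringsAsFactors = FALSE)
  tissue$spot_of_cell <- spot_of_cell
  tissue
}

#' Sample UMI counts from a binned tissue
#'
#' Per-spot, per-gene intensity is the sum over captured cells of
#' `baseline_expression[g] * copy_number[cell, g] / 2` (so a diploid cell
#' contributes its baseline). Spot depth is drawn from a negative binomial
#' around `mean_spot_depth` and counts are multinomial over genes
#' proportional to intensity.
#'
#' @param tissue A binned `synthetic_tissue`.
#' @param config Defaults to `tissue$config`.
#' @return A [spot_counts()] with genes `g0001` ... and section `"sim"`.
#' @export
sample_expression <- function(tissue, config = tissue$config) {
  if (is.null(tissue$spots)) stop("bin_cells_to_spots() first")
  ns <- nrow(tissue$spots); ng <- config$n_genes
  rel <- tissue$genotypes / 2
  intens <- matrix(0, nrow = ns, ncol = ng)
  assigned <- which(!is.na(tissue$spot_of_cell))
  for (i in assigned) {
    s <- tissue$spot_of_cell[i]
    intens[s, ] <- intens[s, ] + rel[tissue$cells$genotype[i], ]
  }
  intens <- sweep(intens, 2, config$baseline_expression, "*")
  counts <- matrix(0L, nrow = ns, ncol = ng)
  if (config$mean_spot_depth > 0) {
    depth <- stats::rnbinom(ns, mu = config$mean_spot_depth,
                            size = config$depth_dispersion)
    for (s in seq_len(ns)) {
      tot <- sum(intens[s, ])
      if (tot == 0) {
        warning("spot ", tissue$spots$barcode[s], " has zero total intensity")
        next
      }
      counts[s, ] <- stats::rmultinom(1, depth[s], intens[s, ] / tot)[, 1]
    }
  }
  dimnames(counts) <- list(tissue$spots$barcode, sprintf("g%04d", seq_len(ng)))
  spot_counts(counts, stats::setNames(rep("sim", ns), tissue$spots$barcode))
}

#' Gene-position table for a simulated tissue
#'
#' All genes sit on one artificial chromosome `chr1`, 1 kb apart.
#'
#' @param config A `sim_config`.
#' @return A `gene_positions` table.
#' @export
simulated_gene_positions <- function(config) {
  ng <- config$n_genes
  gene_positions(data.frame(gene_id = sprintf("g%04d", seq_len(ng)),
                            chromosome = "chr1",
                            start = seq_len(ng) * 1000,
                            stop = seq_len(ng) * 1000 + 500))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Ground truth for a simulated tissue
#'
#' Copy numbers are expressed relative to diploid (`absolute / 2`, so 1 =
#' neutral). Per spot, the mean relative copy number over captured cells is
#' rounded to the nearest integer (ties round half away from zero). Each spot
#' receives the clone (genotype) label carried by the majority of its cells
#' (ties go to the lowest genotype id), and per-clone gene categories follow
#' the rounded clone average: `< 1` deletion, `= 1` neutral, `> 1`
#' amplification.
#'
#' @param tissue A binned `synthetic_tissue`.
#' @return A `ground_truth` list: `spot_mean_copy` and `spot_rounded_copy`
#'   (spot x gene, relative units), `spot_clone` (majority genotype label per
#'   spot), `clone_category` (clone x gene character matrix).
#' @export
ground_truth_categories <- function(tissue) {
  if (is.null(tissue$spots)) stop("bin_cells_to_spots() first")
  ns <- nrow(tissue$spots); ng <- tissue$config$n_genes
  rel <- tissue$genotypes / 2
  mean_copy <- matrix(NA_real_, ns, ng,
                      dimnames = list(tissue$spots$barcode,
                                      sprintf("g%04d", seq_len(ng))))
  spot_clone <- character(ns)
  assigned <- !is.na(tissue$spot_of_cell)
  for (s in seq_len(ns)) {
    cells <- which(assigned & tissue$spot_of_cell == s)
    gt <- tissue$cells$genotype[cells]
    mean_copy[s, ] <- colMeans(rel[gt, , drop = FALSE])
    tab <- table(gt)
    spot_clone[s] <- paste0("clone", names(tab)[which.max(tab)])
  }
  names(spot_clone) <- tissue$spots$barcode
  clones <- sort(unique(spot_clone))
  clone_cat <- matrix(NA_character_, length(clones), ng,
                      dimnames = list(clones, colnames(mean_copy)))
  for (cl in clones) {
    spots_cl <- which(spot_clone == cl)
    cells_cl <- which(assigned & tissue$spot_of_cell %in% spots_cl)
    avg <- colMeans(rel[tissue$cells$genotype[cells_cl], , drop = FALSE])
    clone_cat[cl, ] <- category_from_rounded(round_half_away(avg))
  }
  structure(list(spot_mean_copy = mean_copy,
                 spot_rounded_copy = round_half_away(mean_copy),
                 spot_clone = spot_clone,
                 clone_category = clone_cat),
            class = "ground_truth")
}

#' Ground-truth categories for an arbitrary spot-to-clone assignment
#'
#' Applies the rounded-clone-average rule to externally supplied clone
#' labels (for example the clones inferred by the pipeline), exactly as the
#' synthetic evaluation prescribes.
#'
#' @param tissue A binned `synthetic_tissue`.
#' @param assignment Named character vector: spot barcode -> clone label.
#' @return Clone x gene character matrix of categories.
#' @export
truth_categories_for_assignment <- function(tissue, assignment) {
  if (is.null(tissue$spots)) stop("bin_cells_to_spots() first")
  rel <- tissue$genotypes / 2
  assigned <- !is.na(tissue$spot_of_cell)
  clones <- sort(unique(assignment))
  out <- matrix(NA_character_, length(clones), tissue$config$n_genes,
                dimnames = list(clones, sprintf("g%04d", seq_len(tissue$config$n_genes))))
  for (cl in clones) {
    bcs <- names(assignment)[assignment == cl]
    spots_cl <- match(bcs, tissue$spots$barcode)
    spots_cl <- spots_cl[!is.na(spots_cl)]
    cells_cl <- which(assigned & tissue$spot_of_cell %in% spots_cl)
    if (length(cells_cl) == 0) stop("clone ", cl, " has no captured cells")
    avg <- colMeans(rel[tissue$cells$genotype[cells_cl], , drop = FALSE])
    out[cl, ] <- category_from_rounded(round_half_away(avg))
  }
  out
}

category_from_rounded <- function(r) {
  ifelse(r < 1, "deletion", ifelse(r > 1, "amplification", "neutral"))
}

#' Export a simulated tissue to plain-text files
#'
#' Writes the cell table (CSV), the count matrix (MatrixMarket triplet
#' directory), the spot-by-gene rounded ground-truth copies and the
#' clone-by-gene categories (TSV).
#'
#' @param tissue A binned `synthetic_tissue`.
#' @param counts The matching [spot_counts()] from [sample_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tissue <- function(tissue, counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- ground_truth_categories(tissue)
  cells <- tissue$cells
  cells$clone <- paste0("clone", cells$genotype)
  utils::write.csv(cells[cells$alive,
                         c("id", "x", "y", "parent", "clone")],
                   file.path(dir, "cells.csv"), row.names = FALSE)
  write_count_matrix(counts, file.path(dir, "counts"), format = "mtx")
  utils::write.table(gt$spot_rounded_copy, file.path(dir, "truth_rounded_copy.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(gt$clone_category, file.path(dir, "truth_clone_category.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(dir)
}
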