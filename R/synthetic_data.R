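# Synthetic time-course generator. Datasets carry the statistical structure
# the analysis assumes: expression generated from the temporal-interaction
# model with Gaussian disturbance over the eight developmental days, with
# matching on-disk tracks and annotations so the extraction pipeline can be
# tested end to end without any download.

#' Configuration for the synthetic-data generator
#'
#' Defaults define the study conditions: 30 genes over days
#' `{0, 1, 3, 5, 7, 11, 15, 18}`, Model-4 generation (`f(t) = 0.5^t`) with
#' `beta = (0.5, -0.3, 1.2)`, intercept 0.1 and Gaussian noise sd 0.01.
#' Feature laws: per-gene baseline height `H0 ~ U[1, 10]` decaying
#' exponentially at `height_decay` per day, width `W0 ~ U[50, 500]` growing
#' logarithmically as `W0 (1 + width_growth log10(t + 1))`, and distance
#' drawn fresh per record from `U[0, 1500]` (the time course of distance is
#' disorganized). Distances are integer bp and widths even integer bp so the
#' on-disk representation is exact.
#'
#' @param n_genes Number of genes.
#' @param timepoints Strictly increasing day vector starting at 0.
#' @param beta True coefficients `(beta1, beta2, beta3)`.
#' @param intercept True location of the random disturbance.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param f_t Time function for the distance term (`"0.5^t"` by default,
#'   i.e. Model 4).
#' @param height_decay Exponential decay rate of height per day.
#' @param width_growth Logarithmic growth factor of width.
#' @param seed Integer seed; every draw is reproducible from it.
#' @return An object of class `pc_config`.
#' @export
generative_config <- function(n_genes = 30,
                              timepoints = TIMEPOINTS,
                              beta = c(0.5, -0.3, 1.2),
                              intercept = 0.1,
                              noise_sd = 0.01,
                              f_t = "0.5^t",
                              height_decay = 0.15,
                              width_growth = 0.3,
                              seed = 1) {
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (length(beta) != 3) abort("beta must have length 3")
  if (timepoints[1] != 0 || is.unsorted(timepoints, strictly = TRUE)) {
    abort("timepoints must be strictly increasing and start at 0")
  }
  if (!f_t %in% c("t", "t^2", "t^3", "0.5^t")) abort("f_t must be one of t, t^2, t^3, 0.5^t")
  structure(
    list(
      n_genes = as.integer(n_genes), timepoints = as.integer(timepoints),
      beta = as.numeric(beta), intercept = intercept, noise_sd = noise_sd,
      f_t = f_t, height_decay = height_decay, width_growth = width_growth,
      seed = as.integer(seed)
    ),
    class = "pc_config"
  )
}

# Internal: clamp peak placement so the peak fits inside the 2000-bp promoter
# window (1500 upstream, 500 downstream of the TSS). Returns integer distance.
clamp_distance <- function(distance, width) {
  lo <- pmax(0, width / 2 - 500)
  hi <- 1500 - width / 2
  pmin(pmax(distance, lo), hi)
}

#' Generate a synthetic expression time course
#'
#' Draws per-gene feature trajectories under the configured laws and computes
#' `Exp = beta1 H exp(t) + beta2 D f(t) + beta3 W log10(t+1) + intercept +
#' N(0, sd)`. Fully reproducible from the config seed.
#'
#' @param config A [generative_config()].
#' @return An object of class `pc_sim`: a list with `records` (tibble of
#'   `gene_id`, `day`, `height`, `distance`, `width`, `expression`),
#'   `noiseless` (the deterministic expression values), `clamped` (logical,
#'   peaks whose placement was clamped into the promoter window) and `truth`
#'   (the config).
#' @export
#' @examples
#' sim <- generate_timecourse(generative_config(n_genes = 3, seed = 7))
#' head(sim$records)
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "pc_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    h0 <- runif(config$n_genes, 1, 10)
    w0 <- runif(config$n_genes, 50, 500)
    grid <- tidyr::expand_grid(gene_id = genes, day = config$timepoints)
    gi <- match(grid$gene_id, genes)
    height <- h0[gi] * exp(-config$height_decay * grid$day)
    width_raw <- w0[gi] * (1 + config$width_growth * log10(grid$day + 1))
    width <- 2 * round(width_raw / 2) # even integer bp: exact on-disk midpoint
    distance_raw <- round(runif(nrow(grid), 0, 1500))
    distance <- clamp_distance(distance_raw, width)
    ft <- TIME_FUNCTIONS[[config$f_t]]
    noiseless <- config$beta[1] * height * exp(grid$day) +
      config$beta[2] * distance * ft(grid$day) +
      config$beta[3] * width * log10(grid$day + 1) +
      config$intercept
    noise <- if (config$noise_sd > 0) rnorm(nrow(grid), 0, config$noise_sd) else 0
    records <- tibble(
      gene_id = grid$gene_id,
      day = as.integer(grid$day),
      height = height,
      distance = as.numeric(distance),
      width = as.numeric(width),
      expression = noiseless + noise
    )
    structure(
      list(
        records = records,
        noiseless = noiseless,
        clamped = distance != distance_raw,
        truth = config
      ),
      class = "pc_sim"
    )
  })
}

#' @export
print.pc_sim <- function(x, ...) {
  cat("<pc_sim> ", x$truth$n_genes, " genes x ", length(x$truth$timepoints),
    " days, noise sd ", x$truth$noise_sd, ", seed ", x$truth$seed, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write a synthetic dataset as genomic artifacts
#'
#' Lays the dataset out on one synthetic chromosome: gene `g` (1-based) has
#' its TSS at `10000 * (g + 1)` on alternating strands. For each (gene, day)
#' record a rectangular bedGraph peak of height `H` and width `W` is placed
#' with its midpoint `D` bp upstream of the TSS, inside the promoter window.
#' Writes one bedGraph per day, a BED6 annotation, the expression TSV, and a
#' JSON manifest recording the generative config so the dataset is exactly
#' recomputable.
#'
#' @param sim A `pc_sim` object from [generate_timecourse()].
#' @param dir Output directory (created if needed).
#' @return A list of paths: `tracks` (named by day), `annotation`,
#'   `expression`, `manifest`.
#' @export
write_genomic_artifacts <- function(sim, dir) {
  stopifnot(inherits(sim, "pc_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- unique(sim$records$gene_id)
  chrom <- "chrS"
  tss <- 10000L * (seq_along(genes) + 1L)
  strand <- ifelse(seq_along(genes) %% 2 == 1, "+", "-")
  names(tss) <- names(strand) <- genes

  bed_start <- ifelse(strand == "+", tss, tss - 999L)
  bed_end <- ifelse(strand == "+", tss + 1000L, tss + 1L)
  annotation <- file.path(dir, "genes.bed")
  bed_lines <- if (length(genes) == 0) {
    character(0)
  } else {
    paste(chrom, bed_start, bed_end, genes, 0L, strand, sep = "\t")
  }
  writeLines(bed_lines, annotation)

  tracks <- character(0)
  for (d in sort(unique(sim$records$day))) {
    rows <- sim$records[sim$records$day == d, , drop = FALSE]
    g <- rows$gene_id
    mid <- ifelse(strand[g] == "+", tss[g] - rows$distance, tss[g] + rows$distance)
    start <- as.integer(mid - rows$width / 2)
    end <- as.integer(mid + rows$width / 2)
    ord <- order(start)
    path <- file.path(dir, sprintf("oct4_day%02d.bedGraph", d))
    writeLines(
      c(
        sprintf("track type=bedGraph name=day%d", d),
        paste(chrom, start[ord], end[ord], sprintf("%.17g", rows$height[ord]), sep = "\t")
      ),
      path
    )
    tracks[as.character(d)] <- path
  }

  expression <- file.path(dir, "expression.tsv")
  readr::write_tsv(
    sim$records[c("gene_id", "day", "expression")], expression,
    progress = FALSE
  )

  manifest <- file.path(dir, "dataset_manifest.json")
  jsonlite::write_json(
    list(
      config = unclass(sim$truth),
      clamped_records = sum(sim$clamped),
      files = list(
        annotation = basename(annotation),
        expression = basename(expression),
        tracks = as.list(setNames(basename(tracks), names(tracks)))
      )
    ),
    manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(
    tracks = tracks, annotation = annotation,
    expression = expression, manifest = manifest
  )
}

#' Read a written synthetic dataset back through the extraction pipeline
#'
#' Convenience wrapper: reads the annotation, runs peak derivation and
#' feature extraction on every per-day track, and joins expression. Used to
#' verify the full write-read-extract closure.
#'
#' @param paths The path list returned by [write_genomic_artifacts()].
#' @param min_height Peak threshold passed to [peaks_from_signal()]. Synthetic
#'   tracks carry no background signal, so any positive value recovers the
#'   written peaks; the default is therefore far below generated heights.
#' @return A records tibble.
#' @export
read_genomic_artifacts <- function(paths, min_height = 1e-6) {
  genes <- read_gene_annotation(paths$annotation, "bed6")
  features <- purrr::map_dfr(names(paths$tracks), function(d) {
    track <- read_bedgraph(paths$tracks[[d]])
    extract_features(track, genes, day = as.integer(d), min_height = min_height)
  })
  join_expression(features, read_expression(paths$expression))
}

#' Generate a synthetic classification set with controlled separability
#'
#' Builds records for the high/low classification protocol. The `separation`
#' parameter is the gap, in units of the noise sd, between the noiseless
#' expression values of a high band (30% of genes) and a low band (the rest),
#' realized exactly through the width channel: per record the width is solved
#' so that `beta3 W log10(t+1)` hits the target band value (days exclude 0 so
#' the log term never vanishes; height and distance are drawn at random and
#' carry no signal). A quarter of each band sits exactly on the band's inner
#' edge so the empirical 30%-quantile threshold concentrates inside the gap.
#' With `separation = 0` the generator degenerates to the null model: all
#' coefficients zero and expression equal to the base level plus noise, so
#' labels are unpredictable from the features.
#'
#' @param config A [generative_config()]; `n_genes`, `noise_sd`, `beta[3]`
#'   and `seed` are used. `noise_sd` must be positive.
#' @param separation Gap between bands in noise-sd units (>= 0).
#' @param base_level Center of the expression distribution (default 100).
#' @return A list with `records`, `labels` (by the 30%-quantile rule on
#'   observed expression), `group` (high/mid/low), `threshold`,
#'   `population` (generating band per record) and `truth`.
#' @export
generate_classification_set <- function(config, separation, base_level = 100) {
  stopifnot(inherits(config, "pc_config"))
  if (separation < 0) abort("separation must be >= 0")
  if (config$noise_sd <= 0) abort("classification sets need noise_sd > 0")
  days <- setdiff(config$timepoints, 0L)
  n_genes <- config$n_genes
  n_high_genes <- round(0.3 * n_genes)
  if (n_high_genes < 1 || n_high_genes >= n_genes) abort("n_genes too small")
  with_seed(child_seed(config$seed, 1), {
    genes <- sprintf("g%03d", seq_len(n_genes))
    high_gene <- seq_len(n_genes) <= n_high_genes
    grid <- tidyr::expand_grid(gene_id = genes, day = days)
    gi <- match(grid$gene_id, genes)
    is_high <- high_gene[gi]
    n <- nrow(grid)
    sigma <- config$noise_sd

    band_positions <- function(n_band) {
      n_edge <- ceiling(0.25 * n_band)
      c(rep(0.5, n_edge), 0.5 + runif(n_band - n_edge))
    }
    u <- numeric(n)
    u[is_high] <- band_positions(sum(is_high))
    u[!is_high] <- -band_positions(sum(!is_high))

    height <- runif(n, 1, 10)
    distance <- round(runif(n, 0, 1500))
    if (separation > 0) {
      beta3 <- config$beta[3]
      target <- base_level + separation * sigma * u
      width <- target / (beta3 * log10(grid$day + 1))
      noiseless <- target
      beta_true <- c(0, 0, beta3)
    } else {
      width <- runif(n, 50, 500)
      noiseless <- rep(base_level, n)
      beta_true <- c(0, 0, 0)
    }
    records <- tibble(
      gene_id = grid$gene_id,
      day = as.integer(grid$day),
      height = height,
      distance = as.numeric(distance),
      width = as.numeric(width),
      expression = noiseless + rnorm(n, 0, sigma)
    )
    split <- split_high_low(records$expression, 0.3)
    list(
      records = records,
      labels = split$labels,
      group = split$group,
      threshold = split$threshold,
      population = ifelse(is_high, "high", "low"),
      truth = list(
        config = config, separation = separation, base_level = base_level,
        beta = beta_true, noiseless = noiseless
      )
    )
  })
}
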