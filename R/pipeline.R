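# Orchestration of the full experiment: generate the three data variants,
# train one classifier per variant, explain predictions, cluster relevance
# maps per pair of consecutive age groups, aggregate average maps, and
# score model/reader agreement.

#' Default experiment configuration
#'
#' A desk-scale configuration covering ages 1-9 (juveniles + adolescents)
#' on a 56-pixel canvas so a full run completes in minutes on one CPU; all
#' fields can be overridden and the full 26-class setting is available by
#' widening `ages`. Training follows the standard recipe: adaptive-moment
#' optimiser, batch size 8, learning rate 4e-4, on-the-fly augmentation,
#' softmax cross-entropy.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory recorded in the config.
#' @return an `experiment_config` list.
#' @export
default_config <- function(seed = 1, out_dir = "otolrp-run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    generator = list(
      ages = 1:9, n_per_age = 30, canvas_size = 56,
      split_fraction = 0.2, contrast = 6, target_vertical_extent = 36
    ),
    variants = c("baseline", "binary", "standardized"),
    network = list(conv_filters = c(8, 16, 32), dense_units = 64),
    train = list(batch_size = 8, learning_rate = 4e-4, epochs = 25,
                 augment = FALSE),
    lrp = list(alpha = 1, beta = 0, stabilizer = 1e-9),
    spray = list(out_size = 56, intermediate_size = 112, perplexity = 30,
                 group_source = "predicted", n_permutations = 199),
    write_images = FALSE
  ), class = "experiment_config")
}

#' Write / read an experiment configuration
#'
#' Round-trips the configuration losslessly through a flat YAML file.
#'
#' @param config an `experiment_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  cfg$generator$ages <- as.integer(cfg$generator$ages)
  structure(cfg, class = "experiment_config")
}

# consecutive pairs of the age groups represented among `ages`
group_pairs_for <- function(ages) {
  present <- .age_groups$name[.age_groups$lo <= max(ages) &
                              .age_groups$hi >= min(ages)]
  if (length(present) < 2) return(list())
  lapply(seq_len(length(present) - 1),
         function(i) c(present[i], present[i + 1]))
}

write_csv_plain <- function(d, path) {
  d <- as.data.frame(d)
  d <- d[, !vapply(d, is.list, TRUE), drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE)
}

log_stage <- function(stage, seed, t0, quiet) {
  if (!quiet) {
    message(sprintf("[otolrp] stage=%s seed=%d elapsed=%.1fs",
                    stage, seed, as.numeric(Sys.time()) - t0))
  }
}

#' Run the full experiment
#'
#' Executes generate, train (one model per variant), predict, agreement
#' metrics, relevance propagation, spectral relevance analysis per pair of
#' consecutive age groups, and per-age average maps; writes CSV tables, a
#' JSON report index and (optionally) PNG panels under `out_dir`. Relevance
#' maps are computed for every variant but the binary variant is excluded
#' from clustering: its maps vary only along the otolith contour and carry
#' no inner-structure signal. Fully deterministic given the configuration.
#'
#' @param config an `experiment_config`.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages.
#' @return an `experiment_report`: list of tibbles (`manifest`,
#'   `predictions`, `rmse`, `cv`, `f1`, `embeddings`, `average_maps`),
#'   the trained `models`, `descriptors`, and a `provenance` block.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           quiet = FALSE) {
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())

  st <- stage_generate(config)
  log_stage("generate", config$seed, t0, quiet)
  write_csv_plain(st$manifest, file.path(out_dir, "manifest.csv"))

  st <- stage_train(config, st)
  log_stage("train", config$seed, t0, quiet)
  write_csv_plain(st$train_log, file.path(out_dir, "train_log.csv"))

  st <- stage_metrics(config, st)
  log_stage("metrics", config$seed, t0, quiet)
  write_csv_plain(st$predictions, file.path(out_dir, "predictions.csv"))
  write_csv_plain(st$rmse, file.path(out_dir, "rmse.csv"))
  write_csv_plain(st$cv, file.path(out_dir, "cv.csv"))

  st <- stage_explain(config, st)
  log_stage("explain", config$seed, t0, quiet)

  st <- stage_cluster(config, st)
  log_stage("cluster", config$seed, t0, quiet)
  write_csv_plain(st$f1, file.path(out_dir, "f1.csv"))
  write_csv_plain(st$embeddings, file.path(out_dir, "embeddings.csv"))

  st <- stage_aggregate(config, st)
  log_stage("aggregate", config$seed, t0, quiet)
  write_csv_plain(st$average_maps, file.path(out_dir, "average_maps.csv"))

  report <- stage_report(config, st, out_dir)
  log_stage("report", config$seed, t0, quiet)
  report
}

#' Pipeline stages
#'
#' Individual stages of [run_experiment()]. Each takes the configuration
#' and the state produced by the previous stage and returns the enriched
#' state, so any stage can be rerun independently from persisted state.
#'
#' @param config an `experiment_config`.
#' @param state list produced by the previous stage.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_generate <- function(config) {
  g <- config$generator
  base <- generate_dataset(
    n_per_age = g$n_per_age, ages = g$ages, variant = "baseline",
    canvas_size = g$canvas_size, split_fraction = g$split_fraction,
    seed = derive_seed(config$seed, "generate"), contrast = g$contrast
  )
  datasets <- list()
  for (v in config$variants) {
    datasets[[v]] <- switch(v,
      baseline = base,
      binary = {
        d <- base
        d$train <- lapply(d$train, make_binary)
        d$test <- lapply(d$test, make_binary)
        d$variant <- "binary"
        d
      },
      standardized = {
        d <- base
        d$train <- lapply(d$train, make_standardized,
                          target_vertical_extent = g$target_vertical_extent)
        d$test <- lapply(d$test, make_standardized,
                         target_vertical_extent = g$target_vertical_extent)
        d$variant <- "standardized"
        d
      }
    )
  }
  man <- dplyr::bind_rows(lapply(datasets, manifest))
  list(datasets = datasets, manifest = man)
}

#' @rdname pipeline_stages
#' @export
stage_train <- function(config, state) {
  g <- config$generator
  models <- list()
  logs <- list()
  for (v in config$variants) {
    model <- default_architecture(
      input_shape = c(g$canvas_size, g$canvas_size, 1),
      class_labels = g$ages,
      conv_filters = config$network$conv_filters,
      dense_units = config$network$dense_units,
      seed = derive_seed(config$seed, paste0("init_", v))
    )
    cfg <- train_config(
      batch_size = config$train$batch_size,
      learning_rate = config$train$learning_rate,
      epochs = config$train$epochs,
      seed = derive_seed(config$seed, paste0("train_", v)),
      augment = config$train$augment
    )
    model <- train_network(model, state$datasets[[v]], cfg)
    models[[v]] <- model
    logs[[v]] <- dplyr::mutate(model$train_log, variant = v, .before = 1)
  }
  state$models <- models
  state$train_log <- dplyr::bind_rows(logs)
  state
}

#' @rdname pipeline_stages
#' @export
stage_metrics <- function(config, state) {
  preds <- dplyr::bind_rows(lapply(config$variants, function(v) {
    predict_dataset(state$models[[v]], state$datasets[[v]])
  }))
  rmse_tab <- preds |>
    dplyr::group_by(.data$variant, .data$split) |>
    dplyr::summarise(n = dplyr::n(),
                     rmse = rmse(dplyr::pick(dplyr::everything())),
                     .groups = "drop")
  cv_tab <- mean_cv_by_group(preds)
  state$predictions <- preds
  state$rmse <- rmse_tab
  state$cv <- cv_tab
  state
}

#' @rdname pipeline_stages
#' @export
stage_explain <- function(config, state) {
  params <- rule_params(config$lrp$alpha, config$lrp$beta,
                        config$lrp$stabilizer)
  descriptors <- list()
  for (v in config$variants) {
    ds <- state$datasets[[v]]
    samples <- c(ds$train, ds$test)
    split <- rep(c("train", "test"), c(length(ds$train), length(ds$test)))
    model <- state$models[[v]]
    maps <- vector("list", length(samples))
    preds <- integer(length(samples))
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      m <- compute_relevance_map(model, s$image, params = params,
                                 normalize = TRUE)
      maps[[i]] <- m
      preds[i] <- as.integer(m$target_class)
    }
    meta <- tibble::tibble(
      sample_id = vapply(samples, `[[`, "", "sample_id"),
      read_age = vapply(samples, `[[`, 0L, "age"),
      predicted_age = preds,
      variant = v,
      split = split
    )
    descriptors[[v]] <- make_descriptors(
      maps, lapply(samples, `[[`, "mask"), meta,
      intermediate_size = config$spray$intermediate_size,
      out_size = config$spray$out_size
    )
  }
  state$descriptors <- descriptors
  state
}

subset_descriptors <- function(desc, keep) {
  structure(list(mat = desc$mat[keep, , drop = FALSE],
                 meta = desc$meta[keep, ], out_size = desc$out_size),
            class = "spray_descriptors")
}

#' @rdname pipeline_stages
#' @export
stage_cluster <- function(config, state) {
  cluster_variants <- setdiff(config$variants, "binary")
  pairs <- group_pairs_for(config$generator$ages)
  src <- config$spray$group_source
  f1_rows <- list()
  emb_rows <- list()
  for (v in cluster_variants) {
    desc <- state$descriptors[[v]]
    age_key <- if (src == "predicted") desc$meta$predicted_age else desc$meta$read_age
    groups <- age_group_of(age_key)
    for (pr in pairs) {
      keep <- groups %in% pr
      if (sum(keep) < 5 || length(unique(groups[keep])) < 2) next
      sub <- subset_descriptors(desc, keep)
      sub$meta$group <- factor(groups[keep], levels = pr)
      seed_c <- derive_seed(config$seed, paste0("cluster_", v, "_", pr[1]))
      res <- spray_cluster(sub, seed = seed_c)
      # permutation null: shuffle group labels, keep the partition
      old <- .Random.seed_save()
      set.seed(derive_seed(config$seed, paste0("perm_", v, "_", pr[1])))
      null_f1 <- replicate(config$spray$n_permutations,
                           clustering_f1(res$labels, sample(as.character(sub$meta$group))))
      .Random.seed_restore(old)
      p_value <- (1 + sum(null_f1 >= res$f1)) /
        (1 + config$spray$n_permutations)
      f1_rows[[length(f1_rows) + 1]] <- tibble::tibble(
        variant = v, pair = paste(pr, collapse = "+"),
        n = res$n, k = res$k, f1 = res$f1,
        null_f1_mean = mean(null_f1), p_value = p_value
      )
      emb <- embed_tsne(res$graph,
                        seed = derive_seed(config$seed,
                                           paste0("tsne_", v, "_", pr[1])),
                        perplexity = config$spray$perplexity)
      emb_rows[[length(emb_rows) + 1]] <- tibble::tibble(
        variant = v, pair = paste(pr, collapse = "+"),
        sample_id = sub$meta$sample_id, x = emb$x, y = emb$y,
        predicted_age = sub$meta$predicted_age,
        split = sub$meta$split, cluster = res$labels,
        group = as.character(sub$meta$group)
      )
    }
  }
  state$f1 <- if (length(f1_rows)) dplyr::bind_rows(f1_rows) else
    tibble::tibble(variant = character(0), pair = character(0),
                   n = integer(0), k = integer(0), f1 = numeric(0),
                   null_f1_mean = numeric(0), p_value = numeric(0))
  state$embeddings <- if (length(emb_rows)) dplyr::bind_rows(emb_rows) else
    tibble::tibble()
  state
}

#' @rdname pipeline_stages
#' @export
stage_aggregate <- function(config, state) {
  rows <- list()
  state$average_map_objects <- list()
  for (v in setdiff(config$variants, "binary")) {
    desc <- state$descriptors[[v]]
    counts <- dplyr::count(desc$meta, .data$predicted_age, name = "n")
    groups_present <- unique(age_group_of(desc$meta$predicted_age))
    for (grp in groups_present) {
      show <- select_display_ages(counts, grp)
      for (a in show) {
        keep <- desc$meta$predicted_age == a
        am <- average_relevance_map(subset_descriptors(desc, keep))
        key <- sprintf("%s_age%02d", v, a)
        state$average_map_objects[[key]] <- am
        rows[[length(rows) + 1]] <- dplyr::mutate(
          tidy(am), variant = v, group = grp, .before = 1
        )
      }
    }
  }
  state$average_maps <- dplyr::bind_rows(rows)
  state
}

#' @rdname pipeline_stages
#' @param out_dir directory the report index and images are written to.
#' @export
stage_report <- function(config, state, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (isTRUE(config$write_images)) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (key in names(state$average_map_objects)) {
      write_heatmap_png(state$average_map_objects[[key]],
                        file.path(img_dir, paste0("avg_", key, ".png")))
    }
    suppressMessages(ggplot2::ggsave(
      file.path(img_dir, "cv_bubble.png"), autoplot(state$cv),
      width = 7, height = 4, dpi = 150
    ))
    if (nrow(state$embeddings) > 0) {
      emb <- state$embeddings
      p <- ggplot2::ggplot(emb, ggplot2::aes(x = .data$x, y = .data$y,
                                             colour = .data$group)) +
        ggplot2::geom_point(alpha = 0.8) +
        ggplot2::facet_grid(variant ~ pair) +
        ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = NULL) +
        ggplot2::theme_minimal()
      suppressMessages(ggplot2::ggsave(
        file.path(img_dir, "embeddings.png"), p,
        width = 7, height = 5, dpi = 150
      ))
    }
  }
  provenance <- list(
    package = "otolrp",
    version = as.character(utils::packageVersion("otolrp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config)
  )
  jsonlite::write_json(
    list(provenance = provenance,
         tables = list.files(out_dir, pattern = "\\.csv$")),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  report <- structure(
    list(manifest = state$manifest, train_log = state$train_log,
         predictions = state$predictions, rmse = state$rmse, cv = state$cv,
         f1 = state$f1, embeddings = state$embeddings,
         average_maps = state$average_maps,
         models = state$models, descriptors = state$descriptors,
         average_map_objects = state$average_map_objects,
         provenance = provenance),
    class = "experiment_report"
  )
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d samples, variants: %s\n",
              nrow(x$manifest) , paste(unique(x$manifest$variant), collapse = ", ")))
  if (nrow(x$rmse)) {
    cat("RMSE by variant/split:\n")
    print(as.data.frame(x$rmse))
  }
  if (nrow(x$f1)) {
    cat("Cluster-recovery F1 by pair/variant:\n")
    print(as.data.frame(x$f1[, c("variant", "pair", "n", "f1", "p_value")]))
  }
  invisible(x)
}
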