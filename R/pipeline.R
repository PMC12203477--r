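#' Run the full offline analysis pipeline
#'
#' Generates a synthetic population and a set of sessions for every task,
#' then runs each analysis stage: preprocessing, somatotopy mapping
#' (tuning tables and per-array proportions), movement classification
#' (pooled confusion matrix), velocity decoding under the three array
#' conditions (both/medial/lateral) for the virtual-arm and wrist-imagery
#' cursor tasks, click decoding, and cross-session condition comparisons.
#' Result tables are written as CSV, figures as PNG, and a manifest with the
#' seed and configuration as JSON; the run is deterministic given
#' `(config, seed)`.
#'
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param config A [generator_config()].
#' @param n_sessions Sessions per task.
#' @param seed Master seed; session seeds are derived as small offsets.
#' @param lambda Ridge-penalty policy passed to [loocv_decode()].
#' @param plots Write figure files.
#' @return Invisibly, a list with `tuning`, `proportions`, `classification`,
#'   `decoding`, `comparisons`, `click`, `manifest`.
#' @export
run_pipeline <- function(out_dir = NULL, config = generator_config(),
                         n_sessions = 5L, seed = 1L, lambda = "cv",
                         plots = TRUE) {
  stage <- "population"
  result <- tryCatch({
    pop <- make_population(config, seed = seed)
    conds <- c("both", "medial", "lateral")

    stage <- "somatotopy mapping"
    tuning <- list(); cls <- list(); props <- list()
    for (i in seq_len(n_sessions)) {
      s <- simulate_somatotopy_session(pop, config, seed = seed + 1000L + i)
      sm <- preprocess_session(s)
      tt <- map_tuning(s, sm = sm)
      tt$session <- i
      tuning[[i]] <- tt
      pr <- proportions_by_array(tt)
      pr$session <- i
      props[[i]] <- pr
      cls[[i]] <- classify_movements(s, sm = sm)
    }
    pooled <- pool_confusions(cls)

    stage <- "virtual-arm decoding"
    arm <- list()
    for (i in seq_len(n_sessions)) {
      s <- simulate_reach_grasp_session(pop, config, seed = seed + 2000L + i)
      for (cond in conds) {
        p <- loocv_decode(s, condition = cond, lambda = lambda)
        p$session <- i
        arm[[length(arm) + 1L]] <- as.data.frame(p)
      }
    }

    stage <- "cursor decoding"
    cur <- list()
    for (i in seq_len(n_sessions)) {
      s <- simulate_cursor_session(pop, config, seed = seed + 3000L + i,
                                   imagery = "wrist")
      for (cond in conds) {
        p <- loocv_decode(s, condition = cond, lambda = lambda)
        p$session <- i
        cur[[length(cur) + 1L]] <- as.data.frame(p)
      }
    }
    decoding <- rbind(do.call(rbind, arm), do.call(rbind, cur))

    stage <- "click decoding"
    click <- list()
    for (i in seq_len(n_sessions)) {
      s <- simulate_cursor_session(pop, config, seed = seed + 4000L + i,
                                   imagery = "abstract", clicks = TRUE)
      cd <- decode_click_session(s)
      click[[i]] <- data.frame(session = i, n_epochs = length(cd$per_epoch),
                               click_accuracy = cd$accuracy)
    }
    click <- do.call(rbind, click)

    stage <- "condition comparisons"
    cond_matrix <- function(df, metric) {
      m <- sapply(conds, function(cc) df[[metric]][df$condition == cc])
      rownames(m) <- unique(df$session)
      m
    }
    armdf <- decoding[decoding$task == "reach_grasp", ]
    curdf <- decoding[decoding$task == "cursor_wrist", ]
    comparisons <- list(
      arm_translation = compare_conditions(cond_matrix(armdf, "translation_r2"),
                                           "virtual-arm translation r2"),
      arm_grasp = compare_conditions(cond_matrix(armdf, "grasp_r2"),
                                     "virtual-arm grasp r2"),
      cursor_translation = compare_conditions(cond_matrix(curdf, "translation_r2"),
                                              "wrist-imagery cursor r2"))

    tuning <- do.call(rbind, lapply(tuning, as.data.frame))
    props <- do.call(rbind, props)
    manifest <- list(seed = seed, n_sessions = n_sessions,
                     package_version = as.character(utils::packageVersion("somatodec")),
                     r_version = paste(R.version$major, R.version$minor, sep = "."),
                     lambda = lambda, config = unclass(config))
    list(tuning = tuning, proportions = props, classification = pooled,
         decoding = decoding, click = click, comparisons = comparisons,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(result$tuning, file.path(out_dir, "tuning.csv"),
                     row.names = FALSE)
    utils::write.csv(result$proportions, file.path(out_dir, "proportions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(result$classification$confusion),
                     file.path(out_dir, "confusion.csv"), row.names = FALSE)
    utils::write.csv(result$decoding, file.path(out_dir, "decoding.csv"),
                     row.names = FALSE)
    utils::write.csv(result$click, file.path(out_dir, "click.csv"),
                     row.names = FALSE)
    comp <- do.call(rbind, lapply(names(result$comparisons), function(nm) {
      x <- result$comparisons[[nm]]
      pw <- x$pairwise
      data.frame(comparison = nm, friedman_stat = x$friedman$statistic,
                 friedman_p = x$friedman$p_value,
                 pair = if (is.null(pw)) NA_character_ else pw$pair,
                 wilcoxon_p = if (is.null(pw)) NA_real_ else pw$p_value,
                 significant = if (is.null(pw)) NA else pw$significant)
    }))
    utils::write.csv(comp, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    if (plots) write_pipeline_plots(result, out_dir)
  }
  invisible(structure(result, class = "somatodec_report"))
}

write_pipeline_plots <- function(result, out_dir) {
  grDevices::png(file.path(out_dir, "confusion.png"), 600, 600)
  cm <- result$classification$confusion
  graphics::image(seq_len(ncol(cm)), seq_len(nrow(cm)),
                  t(cm[nrow(cm):1, ]) / rowSums(cm),
                  col = grDevices::hcl.colors(32, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true",
                  main = sprintf("Pooled confusion (accuracy %.1f%%)",
                                 100 * result$classification$overall_accuracy))
  graphics::axis(1, seq_len(ncol(cm)), colnames(cm))
  graphics::axis(2, seq_len(nrow(cm)), rev(rownames(cm)))
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "decoding.png"), 900, 450)
  op <- graphics::par(mfrow = c(1, 2))
  for (tk in unique(result$decoding$task)) {
    sub <- result$decoding[result$decoding$task == tk, ]
    graphics::boxplot(translation_r2 ~ condition, data = sub,
                      ylab = "translation r2", main = tk, ylim = c(0, 1))
  }
  graphics::par(op)
  grDevices::dev.off()

  grDevices::png(file.path(out_dir, "proportions.png"), 700, 450)
  pr <- result$proportions
  agg <- tapply(pr$proportion, list(pr$movement, pr$array_id), mean,
                na.rm = TRUE)
  graphics::barplot(t(agg[movement_labels(), , drop = FALSE]), beside = TRUE,
                    legend.text = TRUE, ylab = "proportion of modulated channels",
                    main = "Tuning proportions by array")
  grDevices::dev.off()
}

#' @export
print.somatodec_report <- function(x, ...) {
  cat("somatodec pipeline report\n")
  cat(sprintf("  pooled movement classification: %.1f%% over %d trials\n",
              100 * x$classification$overall_accuracy, x$classification$n))
  cat(sprintf("  mean click accuracy: %.1f%%\n", 100 * mean(x$click$click_accuracy)))
  for (nm in names(x$comparisons)) print(x$comparisons[[nm]])
  invisible(x)
}
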