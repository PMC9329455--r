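# Delimited-text input/output for trajectory trials and model
# serialization.

#' Write / read trajectory trials as delimited text
#'
#' Two layouts are supported and autodetected by header on read:
#' `wide` (one row per trial: `participant`, `trial`, `condition`,
#' then 3000 `x_*` and 3000 `y_*` sample columns) and `long`
#' (`participant`, `trial`, `condition`, `sample_index`, `x`, `y`; one
#' row per sample).
#'
#' @param trials A list of [trajectory_trial()] objects or a
#'   [simulate_tmaze_dataset()] result.
#' @param path File path (tab-separated text).
#' @param layout `"wide"` or `"long"`.
#' @return `write_trials()`: the path, invisibly. `read_trials()`: a
#'   list of [trajectory_trial()] objects.
#' @export
write_trials <- function(trials, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (inherits(trials, "tmaze_sim")) trials <- trials$trials
  tab <- if (layout == "wide") {
    ids <- do.call(rbind, lapply(trials, function(tr) {
      data.frame(participant = tr$participant, trial = tr$trial,
                 condition = tr$condition)
    }))
    xy <- t(vapply(trials, function(tr) c(tr$x, tr$y), numeric(2L * N_SAMPLES)))
    colnames(xy) <- c(sprintf("x_%04d", seq_len(N_SAMPLES)),
                      sprintf("y_%04d", seq_len(N_SAMPLES)))
    cbind(ids, xy)
  } else {
    do.call(rbind, lapply(trials, function(tr) {
      data.frame(participant = tr$participant, trial = tr$trial,
                 condition = tr$condition,
                 sample_index = seq_len(N_SAMPLES), x = tr$x, y = tr$y)
    }))
  }
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if ("sample_index" %in% names(tab)) { # long layout
    key <- interaction(tab$participant, tab$trial, tab$condition, drop = TRUE)
    lapply(split(tab, key)[unique(key)], function(g) {
      g <- g[order(g$sample_index), ]
      trajectory_trial(g$x, g$y, g$participant[1], g$trial[1], g$condition[1])
    }) |> unname()
  } else if ("x_0001" %in% names(tab)) { # wide layout
    xc <- sprintf("x_%04d", seq_len(N_SAMPLES))
    yc <- sprintf("y_%04d", seq_len(N_SAMPLES))
    lapply(seq_len(nrow(tab)), function(i) {
      trajectory_trial(as.numeric(tab[i, xc]), as.numeric(tab[i, yc]),
                       tab$participant[i], tab$trial[i], tab$condition[i])
    })
  } else {
    stop_domain("unrecognized trial table header (expected wide or long layout)")
  }
}

#' Serialize a fitted classifier
#'
#' Writes the complete fitted model -- spec, all weight and bias
#' arrays, the feature-standardization vectors, configuration and
#' history -- into a single portable container with a format-version
#' tag. The round-trip is bit-exact (`identical()`).
#'
#' @param object A fitted [ffnet()] model.
#' @param path Destination file.
#' @return `write_ffnet()`: the path, invisibly. `read_ffnet()`: the
#'   model.
#' @export
write_ffnet <- function(object, path) {
  stopifnot(inherits(object, "ffnet"))
  saveRDS(list(format = "huangnet_ffnet", version = 1L, model = object),
          path, version = 3L)
  invisible(path)
}

#' @rdname write_ffnet
#' @export
read_ffnet <- function(path) {
  box <- readRDS(path)
  if (!identical(box$format, "huangnet_ffnet")) {
    stop_domain("not a serialized huangnet model")
  }
  if (!identical(box$version, 1L)) {
    stop_domain(sprintf("unsupported model format version %s", box$version))
  }
  box$model
}
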