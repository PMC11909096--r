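## Batch computation over image folders: a stable 46-column measure schema,
## per-image fault isolation, and a single CSV of results.

# registry: measure name -> function(img, ctx) returning one numeric.
# ctx carries shared intermediates (lab, gray, gradient pyramid, edge field,
# conv1 stack, ...) so measures sharing a pipeline stage compute it once.
.measure_registry <- function() {
  lab_ctx <- function(ctx) {
    if (is.null(ctx$lab)) ctx$lab <- convert_color(ctx$img, "lab")
    ctx$lab
  }
  gray_ctx <- function(ctx) {
    if (is.null(ctx$gray)) ctx$gray <- convert_color(ctx$img, "gray8")
    ctx$gray
  }
  hsv_ctx <- function(ctx) {
    if (is.null(ctx$hsv)) ctx$hsv <- convert_color(ctx$img, "hsv")
    ctx$hsv
  }
  stats_ctx <- function(ctx) {
    if (is.null(ctx$chan_stats)) ctx$chan_stats <- color_channel_stats(ctx$img)
    ctx$chan_stats
  }
  phog_ctx <- function(ctx) {
    if (is.null(ctx$phog)) {
      im <- standardize_size(ctx$img, "total_pixels", ctx$params$phog_pixels)
      ctx$phog <- build_phog(gradient_image(im))
    }
    ctx$phog
  }
  edge_ctx <- function(ctx) {
    if (is.null(ctx$edge_field)) {
      ctx$edge_field <- gabor_edge_field(gray_ctx(ctx), ctx$bank_gabor,
                                         max_pixels = ctx$params$gabor_pixels)
    }
    ctx$edge_field
  }
  chan_val <- function(ch, what) {
    function(ctx) {
      s <- stats_ctx(ctx)
      s[[what]][s$channel == ch]
    }
  }
  reg <- list(
    img_size_sum = function(ctx) image_size(ctx$img, "sum"),
    aspect_ratio = function(ctx) aspect_ratio(ctx$img),
    rms_contrast = function(ctx) rms_contrast(lab_ctx(ctx)),
    lightness_entropy = function(ctx) lightness_entropy(lab_ctx(ctx)),
    complexity_hog = function(ctx)
      complexity_hog(ctx$img, resize_to = ctx$params$hog_pixels),
    edge_density = function(ctx) edge_density(edge_ctx(ctx)))
  for (ch in c("R", "G", "B", "L", "a", "b", "H", "S", "V")) {
    reg[[paste0("mean_", ch)]] <- chan_val(ch, "mean")
  }
  for (ch in c("R", "G", "B", "L", "a", "b", "H", "S", "V")) {
    reg[[paste0("std_", ch)]] <- chan_val(ch, "sd")
  }
  reg <- c(reg, list(
    color_entropy = function(ctx) color_entropy(hsv_ctx(ctx)),
    balance = function(ctx)
      balance_score(gray_ctx(ctx), ctx$params$polarity),
    dcm = function(ctx) dcm_score(gray_ctx(ctx), ctx$params$polarity),
    mirror_symmetry = function(ctx) mirror_symmetry(gray_ctx(ctx)),
    homogeneity = function(ctx) homogeneity(gray_ctx(ctx))$final_pct,
    cnn_sym_lr = function(ctx) cnn_symmetry(ctx$img, ctx$bank_cnn, "lr"),
    cnn_sym_ud = function(ctx) cnn_symmetry(ctx$img, ctx$bank_cnn, "ud"),
    cnn_sym_lrud = function(ctx) cnn_symmetry(ctx$img, ctx$bank_cnn, "lrud"),
    fourier_slope_spehar = function(ctx) fourier_slope(ctx$img, "spehar")$slope,
    fourier_slope_redies = function(ctx) fourier_slope(ctx$img, "redies")$slope,
    fourier_slope_mather = function(ctx) fourier_slope(ctx$img, "mather")$slope,
    fourier_sigma = function(ctx) fourier_sigma(ctx$img, binned = FALSE),
    fourier_sigma_binned = function(ctx) fourier_sigma(ctx$img, binned = TRUE),
    fractal_dim_2d = function(ctx) fractal_dim_2d(ctx$img)$D,
    fractal_dim_3d = function(ctx) fractal_dim_3d(ctx$img)$D,
    self_sim_phog = function(ctx) phog_self_similarity(phog_ctx(ctx)),
    self_sim_cnn = function(ctx) cnn_self_similarity(ctx$img, ctx$bank_cnn),
    anisotropy = function(ctx) anisotropy(phog_ctx(ctx)),
    eoe_first = function(ctx) first_order_eoe(edge_ctx(ctx)),
    eoe_second = function(ctx)
      second_order_eoe(strongest_edges(edge_ctx(ctx), ctx$params$eoe_edges)),
    cnn_sparseness = function(ctx) cnn_variances(ctx$img, ctx$bank_cnn)$sparseness,
    cnn_variability = function(ctx) cnn_variances(ctx$img, ctx$bank_cnn)$variability))
  reg
}

.measure_modules <- c(
  img_size_sum = "basic", aspect_ratio = "basic", rms_contrast = "basic",
  lightness_entropy = "basic", complexity_hog = "hog", edge_density = "gabor",
  color_entropy = "basic", balance = "balance", dcm = "balance",
  mirror_symmetry = "balance", homogeneity = "balance",
  cnn_sym_lr = "cnn", cnn_sym_ud = "cnn", cnn_sym_lrud = "cnn",
  fourier_slope_spehar = "spectral", fourier_slope_redies = "spectral",
  fourier_slope_mather = "spectral", fourier_sigma = "spectral",
  fourier_sigma_binned = "spectral", fractal_dim_2d = "spectral",
  fractal_dim_3d = "spectral", self_sim_phog = "hog", self_sim_cnn = "cnn",
  anisotropy = "hog", eoe_first = "gabor", eoe_second = "gabor",
  cnn_sparseness = "cnn", cnn_variability = "cnn")

#' List the measure schema
#'
#' Every measure name the batch runner can compute, with its module and
#' default parameters. The names are exactly the CSV columns of
#' [run_batch], in order.
#'
#' @return data frame with columns `measure`, `module`, `parameters`.
#' @export
list_measures <- function() {
  nm <- names(.measure_registry())
  module <- ifelse(grepl("^(mean|std)_", nm), "basic",
                   unname(.measure_modules[nm]))
  pars <- character(length(nm))
  pars[nm == "complexity_hog"] <- "hog_pixels (default 100000)"
  pars[nm %in% c("self_sim_phog", "anisotropy")] <- "phog_pixels (default 100000)"
  pars[nm %in% c("edge_density", "eoe_first")] <- "gabor_pixels (default 120000)"
  pars[nm == "eoe_second"] <- "gabor_pixels; eoe_edges (default 10000)"
  pars[nm %in% c("balance", "dcm")] <- "polarity (default dark_heavy)"
  pars[grepl("^cnn_", nm) | nm == "self_sim_cnn"] <- "cnn_weights (optional asset)"
  data.frame(measure = nm, module = module, parameters = pars)
}

.default_params <- function() {
  list(hog_pixels = 100000, phog_pixels = 100000, gabor_pixels = 120000,
       eoe_edges = 10000L, polarity = "dark_heavy")
}

#' Compute selected measures for one image
#'
#' @param img a [qip_image].
#' @param measures character vector of measure names (see [list_measures]),
#'   or `"all"`.
#' @param params named list overriding the defaults of
#'   `qipr:::.default_params()`.
#' @param cnn_bank a `qip_filter_bank`; default is the seeded surrogate.
#' @param gabor_bank_obj a `qip_gabor_bank`.
#' @return named numeric vector (NaN propagates from degenerate measures).
#' @export
compute_measures <- function(img, measures = "all", params = list(),
                             cnn_bank = NULL, gabor_bank_obj = NULL) {
  reg <- .measure_registry()
  if (identical(measures, "all")) measures <- names(reg)
  bad <- setdiff(measures, names(reg))
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(.default_params(), params)
  ctx <- new.env(parent = emptyenv())
  ctx$img <- img
  ctx$params <- p
  need_cnn <- any(grepl("^cnn_|^self_sim_cnn$", measures))
  ctx$bank_cnn <- if (!is.null(cnn_bank)) cnn_bank
                  else if (need_cnn) surrogate_filter_bank(1L) else NULL
  ctx$bank_gabor <- if (!is.null(gabor_bank_obj)) gabor_bank_obj
                    else gabor_bank()
  out <- vapply(measures, function(m) as.numeric(reg[[m]](ctx)), numeric(1))
  names(out) <- measures
  out
}

#' Run a batch of images and write one CSV of measures
#'
#' One row per input image, rows in sorted-path order; a failing image
#' yields a row of NA values plus a reason in the `error` column while the
#' remaining images are still processed. NA is encoded as an empty cell;
#' the CSV uses '.' decimal points, UTF-8 and LF line endings regardless of
#' locale.
#'
#' @param input character vector of image files and/or directories
#'   (directories are scanned for png/jpg/jpeg/tif/tiff).
#' @param measures `"all"` or a subset of `list_measures()$measure`.
#' @param out path of the CSV to write, or `NULL` to skip writing.
#' @param params named list of parameter overrides (see [compute_measures]).
#' @param seed integer seed controlling the surrogate filter bank.
#' @param cnn_weights optional path of a pretrained conv1 tensor asset.
#' @param log_level `"info"` or `"quiet"`.
#' @return data frame of results, invisibly; attribute `"n_failed"` counts
#'   failed images.
#' @export
run_batch <- function(input, measures = "all", out = NULL, params = list(),
                      seed = 1L, cnn_weights = NULL,
                      log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  reg_names <- names(.measure_registry())
  if (identical(measures, "all")) measures <- reg_names
  bad <- setdiff(measures, reg_names)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "))
  files <- unlist(lapply(input, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                 ignore.case = TRUE, full.names = TRUE)
    } else p
  }))
  files <- sort(unique(files))
  if (length(files) == 0L) stop("no input images")
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("input not found: ", paste(missing, collapse = ", "))
  if (!is.null(out)) {
    ok <- tryCatch({ con <- file(out, "w"); close(con); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("output path not writable: ", out)
  }
  need_cnn <- any(grepl("^cnn_|^self_sim_cnn$", measures))
  bank <- if (!is.null(cnn_weights)) load_filter_bank(cnn_weights)
          else if (need_cnn) surrogate_filter_bank(as.integer(seed)) else NULL
  gbank <- gabor_bank()
  note <- function(...) if (log_level == "info") message(sprintf(...))
  rows <- lapply(files, function(f) {
    note("processing %s", f)
    res <- tryCatch({
      img <- load_image(f)
      vals <- suppressWarnings(
        compute_measures(img, measures, params, cnn_bank = bank,
                         gabor_bank_obj = gbank))
      c(as.list(vals), list(error = NA_character_))
    }, error = function(e) {
      note("  FAILED: %s", conditionMessage(e))
      v <- as.list(rep(NA_real_, length(measures)))
      names(v) <- measures
      c(v, list(error = conditionMessage(e)))
    })
    data.frame(image = basename(f), res, stringsAsFactors = FALSE,
               check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  n_failed <- sum(!is.na(df$error))
  if (!is.null(out)) {
    con <- file(out, open = "wb", encoding = "UTF-8")
    utils::write.csv(df, con, row.names = FALSE, na = "", eol = "\n")
    close(con)
    note("wrote %d rows (%d failed) to %s", nrow(df), n_failed, out)
  }
  attr(df, "n_failed") <- n_failed
  invisible(df)
}
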