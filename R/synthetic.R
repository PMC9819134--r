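#' Specify one compound peak of a synthetic chromatogram
#'
#' A `peak_spec` describes a single eluting compound as a Gaussian peak:
#' its nominal retention-time center and jitter, its mean height with a
#' lognormal-free multiplicative spread, and its Gaussian sigma (width).
#'
#' @param compound_name character label of the compound.
#' @param rt_center nominal elution time, minutes.
#' @param height_mean mean peak height, detector units (> 0).
#' @param rt_jitter_sd SD of the per-sample retention-time jitter, minutes.
#' @param height_cv coefficient of variation of the realized height.
#' @param width_sd Gaussian sigma of the peak shape, minutes (> 0).
#' @return An object of class `"peak_spec"`.
#' @export
peak_spec <- function(compound_name, rt_center, height_mean,
                      rt_jitter_sd = 0, height_cv = 0, width_sd = 0.04) {
  if (height_mean <= 0) stop_fmt("height_mean must be > 0")
  if (rt_jitter_sd < 0) stop_fmt("rt_jitter_sd must be >= 0")
  if (height_cv < 0) stop_fmt("height_cv must be >= 0")
  if (width_sd <= 0) stop_fmt("width_sd must be > 0")
  structure(list(compound_name = as.character(compound_name)[1],
                 rt_center = as.double(rt_center),
                 rt_jitter_sd = as.double(rt_jitter_sd),
                 height_mean = as.double(height_mean),
                 height_cv = as.double(height_cv),
                 width_sd = as.double(width_sd)),
            class = "peak_spec")
}

#' Specify a latent class of a synthetic cohort
#'
#' A class owns a set of `unique_peaks` (compounds only its members exhale)
#' on top of the cohort-wide `shared_peaks`; each unique peak appears in a
#' given member with probability `unique_presence_prob`.
#'
#' @param class_id integer class label, 0-based.
#' @param size number of samples in the class (>= 1).
#' @param shared_peaks list of [peak_spec()] present in every class.
#' @param unique_peaks list of [peak_spec()] present only in this class.
#' @param unique_presence_prob probability that each unique peak appears in a
#'   given sample of the class.
#' @return An object of class `"class_template"`.
#' @export
class_template <- function(class_id, size, shared_peaks, unique_peaks,
                           unique_presence_prob = 1.0) {
  if (!is_count(size) || size < 1) stop_fmt("class size must be a count >= 1")
  if (unique_presence_prob < 0 || unique_presence_prob > 1)
    stop_fmt("unique_presence_prob must lie in [0, 1]")
  structure(list(class_id = as.integer(class_id), size = as.integer(size),
                 shared_peaks = shared_peaks, unique_peaks = unique_peaks,
                 unique_presence_prob = as.double(unique_presence_prob)),
            class = "class_template")
}

#' Describe a full synthetic cohort scenario
#'
#' The scenario is the complete generative description of a cohort: latent
#' classes with their peak templates, the retention axis, baseline and noise
#' model, and the master seed. It is the ground truth that recovery tests
#' compare against.
#'
#' @param class_templates list of [class_template()]s; unique-peak compound
#'   names must be pairwise disjoint across classes.
#' @param rt_start,rt_end retention-axis limits, minutes (`rt_end > rt_start`).
#' @param sampling_rate grid density, points per minute (> 0).
#' @param baseline_level constant baseline intensity, detector units.
#' @param baseline_drift_slope linear baseline drift, detector units / minute.
#' @param noise_sd SD of additive Gaussian detector noise (>= 0).
#' @param seed master seed; the cohort is a pure function of the scenario.
#' @param name scenario label.
#' @return An object of class `"cohort_scenario"`, with `n_samples` equal to
#'   the sum of class sizes.
#' @seealso [default_scenario()], [generate_cohort()]
#' @export
cohort_scenario <- function(class_templates, rt_start, rt_end, sampling_rate,
                            baseline_level = 0, baseline_drift_slope = 0,
                            noise_sd = 0, seed = 1L, name = "custom") {
  if (rt_end <= rt_start) stop_fmt("rt_end must exceed rt_start")
  if (sampling_rate <= 0) stop_fmt("sampling_rate must be > 0")
  if (noise_sd < 0) stop_fmt("noise_sd must be >= 0")
  uniq <- lapply(class_templates, function(tpl)
    vapply(tpl$unique_peaks, function(p) p$compound_name, character(1)))
  all_uniq <- unlist(uniq)
  if (anyDuplicated(all_uniq))
    stop_fmt("unique-peak compound names must be disjoint across classes ('%s' repeats)",
             all_uniq[duplicated(all_uniq)][1])
  for (tpl in class_templates) {
    rts <- vapply(c(tpl$shared_peaks, tpl$unique_peaks),
                  function(p) p$rt_center, double(1))
    if (length(rts) && (any(rts < rt_start) || any(rts > rt_end)))
      stop_fmt("peak rt_center outside the retention axis in class %d", tpl$class_id)
  }
  structure(list(name = as.character(name)[1],
                 n_samples = sum(vapply(class_templates, function(t) t$size, integer(1))),
                 class_templates = class_templates,
                 rt_start = as.double(rt_start), rt_end = as.double(rt_end),
                 sampling_rate = as.double(sampling_rate),
                 baseline_level = as.double(baseline_level),
                 baseline_drift_slope = as.double(baseline_drift_slope),
                 noise_sd = as.double(noise_sd),
                 seed = as.integer(seed)),
            class = "cohort_scenario")
}

#' @export
print.cohort_scenario <- function(x, ...) {
  sizes <- vapply(x$class_templates, function(t) t$size, integer(1))
  cat(sprintf("<cohort_scenario> '%s': %d samples in %d classes (%s), rt %.2f-%.2f min @ %g pts/min, noise_sd %g, seed %d\n",
              x$name, x$n_samples, length(sizes),
              paste(sizes, collapse = "/"), x$rt_start, x$rt_end,
              x$sampling_rate, x$noise_sd, x$seed))
  invisible(x)
}

# Shared breath VOCs used for the 12 cohort-wide peaks of the built-in
# scenario: classic exhaled-air compounds.
.bnp37_shared <- function() {
  specs <- list(
    list("Acetaldehyde",      1.8, 15000),
    list("Ethanol",           4.2, 26000),
    list("Acetone",           6.5, 52000),
    list("Isoprene",          9.0, 34000),
    list("Dimethyl sulfide", 12.3,  6500),   # below the 10,000 filter
    list("Pentane",          15.7, 18000),
    list("Benzene",          19.4,  8800),   # below the 10,000 filter
    list("Toluene",          23.1, 24000),
    list("Hexanal",          27.6, 13000),
    list("Styrene",          33.2, 30000),
    list("Limonene",         40.5, 42000),
    list("2-Propanol",       47.8, 20000)
  )
  lapply(specs, function(s)
    peak_spec(s[[1]], s[[2]], s[[3]], rt_jitter_sd = 0.015,
              height_cv = 0.03, width_sd = 0.04))
}

# Unique compounds per latent class; names drawn from published per-cluster
# breath-phase compound lists (see inst/extdata/pah_cluster_compounds.tsv).
# The latent classes emulate distinct metabolic phenotypes: each class's
# unique compounds occupy a class-specific retention band (where in the run
# they elute), follow a class-specific abundance ladder (how much of them is
# exhaled, the last one being the class's dominant compound) and share a
# class-specific peak width. Band order, abundance order and width order are
# deliberately decoupled across classes, so no single axis orders the four
# phenotypes and the class centroids sit roughly equidistant in profile
# space rather than along one gradient.
.bnp37_unique <- function() {
  list(
    list(  # class 0: early band, mid-low abundance, mid-wide peaks
      list("Methanone",                     5.5, 40000),
      list("Diethyl Phthalate",             8.3, 47000),
      list("1-Undecene, 4-methyl-",        11.6, 54000),
      list("1-Bromo-4-bromomethyldecane",  14.8, 61000),
      list("3-Hydroxy-dl-kynurenine",      18.5, 68000),
      list("Thymol blue",                  22.0, 95000)),
    list(  # class 1: early-mid band, high abundance, narrow peaks
      list("1-Tetradecanol",               16.5, 60000),
      list("Cyclotrisiloxane, hexamethyl-",21.3, 71000),
      list("Arabinitol, pentaacetate",     25.4, 82000),
      list("Dibutyl phthalate",            28.8, 93000),
      list("Silicone oil",                 31.9, 104000),
      list("Dotriacontane",                35.0, 115000)),
    list(  # class 2: mid-late band, low abundance, mid-narrow peaks
      list("1H,1H,2H,2H-Perfluorooctyl iodide", 26.2, 30000),
      list("Me-t-BDMS of LTB4",            30.4, 35000),
      list("Quinovic Acid",                34.3, 40000),
      list("butyl decanoate",              38.7, 45000),
      list("1,3,4-Tribromo-2,5-dichlorobenzene", 42.6, 50000),
      list("Podocarpan-14.beta.-ol",       45.9, 90000)),
    list(  # class 3: late band, mid-high abundance, broad peaks
      list("1,4-Diethylpiperazine",        36.8, 50000),
      list("Chloroform",                   41.2, 59000),
      list("Acenaphthylene",               44.8, 68000),
      list("Octasiloxane",                 48.3, 77000),
      list("Stannane, tetrapropyl-",       50.2, 86000),
      list("Clomipramine",                 51.8, 100000))
  )
}

# class-specific Gaussian sigma of unique peaks, minutes (order decoupled
# from both the band order and the abundance order)
.bnp37_unique_width <- c(0.046, 0.030, 0.038, 0.054)

#' The built-in "bnp37" cohort scenario
#'
#' A 37-sample synthetic breath-chromatogram cohort with four latent classes
#' of sizes 10, 8, 11 and 8, emulating a GC/MS breathomics study of a
#' pulmonary-arterial-hypertension registry cohort. Each sample carries 12
#' shared breath-VOC peaks (two below and one near the 10,000-unit intensity
#' filter) plus 6 class-unique compound peaks well above it, on a
#' 0.5-52.75 min retention axis sampled at 120 points/min, over a drifting
#' baseline with Gaussian detector noise.
#'
#' @param seed master seed of the scenario (default 20221228).
#' @return A [cohort_scenario()] with `n_samples = 37`.
#' @examples
#' sc <- default_scenario()
#' sc$n_samples
#' vapply(sc$class_templates, function(t) t$size, integer(1))
#' @export
default_scenario <- function(seed = 20221228L) {
  shared <- .bnp37_shared()
  uniq <- .bnp37_unique()
  sizes <- c(10L, 8L, 11L, 8L)
  templates <- lapply(seq_along(sizes), function(i) {
    up <- lapply(uniq[[i]], function(s)
      peak_spec(s[[1]], s[[2]], s[[3]], rt_jitter_sd = 0.015,
                height_cv = 0.03, width_sd = .bnp37_unique_width[i]))
    class_template(i - 1L, sizes[i], shared, up, unique_presence_prob = 1.0)
  })
  cohort_scenario(templates, rt_start = 0.5, rt_end = 52.75,
                  sampling_rate = 120, baseline_level = 2000,
                  baseline_drift_slope = 30, noise_sd = 400,
                  seed = seed, name = "bnp37")
}

rt_grid <- function(scenario) {
  seq(scenario$rt_start, scenario$rt_end, by = 1 / scenario$sampling_rate)
}

#' Generate a single synthetic chromatogram
#'
#' Realizes one sample from a class template: a linear baseline plus one
#' Gaussian per peak (height drawn with the spec's coefficient of variation
#' and truncated at 10% of its mean; center jittered), plus additive Gaussian
#' detector noise, clipped at zero.
#'
#' @param template a [class_template()] belonging to `scenario`.
#' @param scenario the [cohort_scenario()].
#' @param sample_id identifier for the generated sample.
#' @param seed RNG seed for this sample's realization.
#' @return A list: `chromatogram` (a [chromatogram()]) and `compounds`
#'   (data.frame `sample_id`, `compound_name`, `rt` of the peaks actually
#'   placed).
#' @export
generate_chromatogram <- function(template, scenario, sample_id, seed) {
  found <- any(vapply(scenario$class_templates, identical, logical(1), template))
  if (!found) stop_fmt("template (class_id %d) is not part of the scenario",
                       template$class_id)
  rt <- rt_grid(scenario)
  with_seed(seed, {
    y <- scenario$baseline_level + scenario$baseline_drift_slope * rt
    placed <- list()
    place <- function(spec) {
      h <- spec$height_mean * (1 + spec$height_cv * stats::rnorm(1))
      h <- max(h, 0.1 * spec$height_mean)
      cen <- spec$rt_center +
        if (spec$rt_jitter_sd > 0) stats::rnorm(1, 0, spec$rt_jitter_sd) else 0
      y <<- y + h * exp(-(rt - cen)^2 / (2 * spec$width_sd^2))
      placed[[length(placed) + 1L]] <<-
        data.frame(sample_id = sample_id, compound_name = spec$compound_name,
                   rt = cen, stringsAsFactors = FALSE)
    }
    for (spec in template$shared_peaks) place(spec)
    for (spec in template$unique_peaks) {
      if (stats::runif(1) <= template$unique_presence_prob) place(spec)
      else { # burn the draws a placed peak would take: keeps streams aligned
        stats::rnorm(1)
        if (spec$rt_jitter_sd > 0) stats::rnorm(1)
      }
    }
    if (scenario$noise_sd > 0)
      y <- y + stats::rnorm(length(rt), 0, scenario$noise_sd)
    y <- pmax(y, 0)
    compounds <- if (length(placed)) do.call(rbind, placed)
      else data.frame(sample_id = character(0), compound_name = character(0),
                      rt = double(0), stringsAsFactors = FALSE)
    list(chromatogram = chromatogram(rt, y, sample_id), compounds = compounds)
  })
}

#' Generate a full synthetic cohort
#'
#' Emits one chromatogram per sample in class order, the ground-truth class
#' label of each sample, and the compound-annotation table of every peak
#' actually placed. Fully reproducible from `scenario$seed`: each sample uses
#' a fixed sub-stream of the master seed, so the cohort does not depend on
#' generation order.
#'
#' @param scenario a [cohort_scenario()].
#' @return A list with elements `chromatograms` (list of [chromatogram()]),
#'   `labels` (integer vector, 0-based class ids), `compounds` (data.frame
#'   `sample_id`, `compound_name`, `rt`) and `scenario`.
#' @examples
#' sc <- default_scenario()
#' cohort <- generate_cohort(sc)
#' table(cohort$labels)
#' @export
generate_cohort <- function(scenario) {
  if (!inherits(scenario, "cohort_scenario")) stop_fmt("not a cohort_scenario")
  chroms <- vector("list", scenario$n_samples)
  labels <- integer(scenario$n_samples)
  comp <- vector("list", scenario$n_samples)
  i <- 0L
  for (tpl in scenario$class_templates) {
    for (j in seq_len(tpl$size)) {
      i <- i + 1L
      sid <- sprintf("S%02d", i)
      out <- generate_chromatogram(tpl, scenario, sid,
                                   substream_seed(scenario$seed, i))
      chroms[[i]] <- out$chromatogram
      comp[[i]] <- out$compounds
      labels[i] <- tpl$class_id
    }
  }
  names(chroms) <- vapply(chroms, function(c) c$sample_id, character(1))
  list(chromatograms = chroms, labels = labels,
       compounds = do.call(rbind, comp), scenario = scenario)
}

#' Serialize / deserialize a cohort scenario as JSON
#'
#' @param scenario a [cohort_scenario()].
#' @param path file path to write to / read from.
#' @return `read_scenario` returns a [cohort_scenario()]; `write_scenario`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass_deep(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  templates <- lapply(raw$class_templates, function(t) {
    mk <- function(p) peak_spec(p$compound_name, p$rt_center, p$height_mean,
                                p$rt_jitter_sd, p$height_cv, p$width_sd)
    class_template(t$class_id, t$size, lapply(t$shared_peaks, mk),
                   lapply(t$unique_peaks, mk), t$unique_presence_prob)
  })
  cohort_scenario(templates, raw$rt_start, raw$rt_end, raw$sampling_rate,
                  raw$baseline_level, raw$baseline_drift_slope, raw$noise_sd,
                  raw$seed, raw$name)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
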