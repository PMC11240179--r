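#' Describe one topic of a synthetic corpus
#'
#' A topic bundles everything the generator needs to emit papers of one
#' discipline: a vocabulary with sampling weights, the journal-title keyword
#' that downstream labelling should recover, a Gaussian publication-year
#' distribution (drift centre and spread), a female-proportion-by-year
#' function for author forenames, and a retraction rate.
#'
#' @param name topic name; also the default journal keyword.
#' @param vocabulary character vector of topic-specific words.
#' @param vocab_weights positive sampling weights, recycled to the
#'   vocabulary length; default uniform.
#' @param journal_keyword word embedded in generated journal titles.
#' @param year_mean,year_sd centre and spread of the topic's publication
#'   years (rounded to integers, truncated to the config's year range).
#' @param prop_female either a single proportion in `[0, 1]` or a function
#'   of calendar year returning one.
#' @param retraction_rate probability in `[0, 1]` that a paper is flagged
#'   retracted.
#' @param weight relative share of the corpus drawn from this topic.
#' @return a `synthetic_topic` list.
#' @export
synthetic_topic <- function(name, vocabulary,
                            vocab_weights = NULL,
                            journal_keyword = name,
                            year_mean = 2005, year_sd = 8,
                            prop_female = 0.4,
                            retraction_rate = 0.01,
                            weight = 1) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(vocabulary), length(vocabulary) >= 1)
  if (retraction_rate < 0 || retraction_rate > 1) {
    stop("`retraction_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (is.numeric(prop_female)) {
    if (prop_female < 0 || prop_female > 1) {
      stop("`prop_female` must lie in [0, 1]", call. = FALSE)
    }
    p <- prop_female
    prop_female <- function(year) rep(p, length(year))
  }
  stopifnot(is.function(prop_female))
  w <- if (is.null(vocab_weights)) rep(1, length(vocabulary)) else
    rep_len(vocab_weights, length(vocabulary))
  if (any(w < 0)) stop("`vocab_weights` must be nonnegative", call. = FALSE)
  structure(
    list(name = name, vocabulary = vocabulary, vocab_weights = w,
         journal_keyword = journal_keyword,
         year_mean = year_mean, year_sd = year_sd,
         prop_female = prop_female,
         retraction_rate = retraction_rate, weight = weight),
    class = "synthetic_topic"
  )
}

#' Default topic set for synthetic corpora
#'
#' Five disciplines whose journal keywords come from the built-in label
#' list, each with its own vocabulary, year drift, gender trajectory and
#' retraction rate. These defaults define the study conditions the rest of
#' the package is exercised under.
#'
#' @return list of [synthetic_topic()] objects.
#' @export
default_topics <- function() {
  list(
    synthetic_topic(
      "neuroscience",
      c("neuron", "cortex", "synapse", "dendrite", "axon", "glia",
        "hippocampus", "plasticity", "spike", "channel", "receptor",
        "circuit", "dopamine", "memory", "electrophysiology", "cortical",
        "inhibition", "excitatory", "imaging", "stimulus"),
      year_mean = 2000, year_sd = 10,
      prop_female = function(year) pmin(0.6, 0.1 + 0.008 * (year - 1970)),
      retraction_rate = 0.005
    ),
    synthetic_topic(
      "surgery",
      c("resection", "laparoscopic", "incision", "suture", "anastomosis",
        "postoperative", "operative", "graft", "transplantation",
        "complication", "hernia", "catheter", "anesthesia", "hemorrhage",
        "ligament", "fracture", "implant", "wound", "drainage", "stent"),
      year_mean = 1995, year_sd = 12,
      prop_female = function(year) pmin(0.45, 0.05 + 0.006 * (year - 1970)),
      retraction_rate = 0.005
    ),
    synthetic_topic(
      "virology",
      c("virus", "viral", "capsid", "genome", "replication", "infection",
        "antibody", "vaccine", "epitope", "serotype", "pathogen",
        "influenza", "titer", "antigen", "outbreak", "transmission",
        "mutation", "strain", "host", "immunity"),
      year_mean = 2010, year_sd = 7,
      prop_female = function(year) pmin(0.55, 0.15 + 0.007 * (year - 1970)),
      retraction_rate = 0.01
    ),
    synthetic_topic(
      "psychology",
      c("cognitive", "behavior", "anxiety", "depression", "emotion",
        "perception", "attention", "personality", "stress", "therapy",
        "questionnaire", "wellbeing", "motivation", "adolescent", "mood",
        "cognition", "social", "bias", "learning", "memory"),
      year_mean = 2008, year_sd = 9,
      prop_female = function(year) pmin(0.7, 0.2 + 0.009 * (year - 1970)),
      retraction_rate = 0.005
    ),
    synthetic_topic(
      "cancer",
      c("tumor", "oncogene", "metastasis", "carcinoma", "apoptosis",
        "chemotherapy", "biomarker", "proliferation", "malignant",
        "mutation", "lymphoma", "melanoma", "microrna", "osteosarcoma",
        "pathway", "radiotherapy", "biopsy", "prognosis", "survival",
        "angiogenesis"),
      year_mean = 2012, year_sd = 6,
      prop_female = function(year) pmin(0.55, 0.15 + 0.007 * (year - 1970)),
      retraction_rate = 0.05
    )
  )
}

# Shared filler words mixed into every topic's abstracts so that documents
# overlap in vocabulary the way real abstracts do.
stopword_pool <- function() {
  c("the", "of", "and", "in", "to", "we", "with", "for", "was", "were",
    "is", "are", "that", "this", "these", "results", "study", "analysis",
    "method", "data", "patients", "significant", "observed", "compared",
    "between", "group", "using", "showed", "effect", "levels")
}

#' Configuration of a synthetic corpus
#'
#' Collects the generator settings: corpus size, the topic list, the
#' between-cluster separation used in vector mode (centre distance in units
#' of within-cluster standard deviation), the vector dimensionality, and the
#' master seed from which every stage derives its own child seed.
#'
#' @param n_papers number of papers (>= 0).
#' @param topics list of [synthetic_topic()] objects.
#' @param cluster_separation nonnegative scalar; pairwise distance between
#'   Gaussian cluster centres in within-cluster s.d. units (vector mode).
#' @param dim vector dimensionality (vector mode).
#' @param seed integer master seed.
#' @param year_range integer vector of length 2; generated years are
#'   truncated to this range.
#' @param min_chars,max_chars abstract length bounds enforced by the text
#'   generator (defaults match the ingest filter's 250-4000 window).
#' @param name_table [name_gender_table()] used to draw author forenames.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_papers,
                             topics = default_topics(),
                             cluster_separation = 6,
                             dim = 50,
                             seed = 1,
                             year_range = c(1970, 2021),
                             min_chars = 250,
                             max_chars = 4000,
                             name_table = builtin_name_table()) {
  n_papers <- assert_scalar_count(n_papers, "n_papers", min = 0)
  if (!is.list(topics) || !all(vapply(topics, inherits, TRUE,
                                      "synthetic_topic"))) {
    stop("`topics` must be a list of synthetic_topic objects", call. = FALSE)
  }
  if (!is.numeric(cluster_separation) || cluster_separation < 0) {
    stop("`cluster_separation` must be >= 0", call. = FALSE)
  }
  dim <- assert_scalar_count(dim, "dim", min = 1)
  stopifnot(length(year_range) == 2, year_range[1] <= year_range[2])
  structure(
    list(n_papers = n_papers, topics = topics,
         cluster_separation = cluster_separation, dim = dim,
         seed = as.integer(seed), year_range = as.integer(year_range),
         min_chars = min_chars, max_chars = max_chars,
         name_table = name_table),
    class = "synthetic_config"
  )
}

#' Read a synthetic-corpus configuration from a YAML file
#'
#' The file holds top-level keys (`n_papers`, `cluster_separation`, `dim`,
#' `seed`, `year_range`) and a `topics` block, one entry per topic with the
#' fields of [synthetic_topic()]. `prop_female` may be a single number or a
#' mapping `{from: p0, to: p1}` interpreted as a linear trajectory over
#' `year_range`.
#'
#' @param path file path.
#' @return a [synthetic_config()].
#' @export
read_synthetic_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  year_range <- as.integer(cfg$year_range %||% c(1970, 2021))
  mk_pf <- function(pf) {
    if (is.null(pf)) return(0.4)
    if (is.numeric(pf) && length(pf) == 1) return(pf)
    stopifnot(!is.null(pf$from), !is.null(pf$to))
    from <- pf$from; to <- pf$to; y0 <- year_range[1]; y1 <- year_range[2]
    function(year) {
      t <- pmin(1, pmax(0, (year - y0) / max(1, y1 - y0)))
      from + t * (to - from)
    }
  }
  topics <- lapply(cfg$topics, function(tp) {
    synthetic_topic(
      name = tp$name,
      vocabulary = as.character(tp$vocabulary),
      vocab_weights = tp$vocab_weights,
      journal_keyword = tp$journal_keyword %||% tp$name,
      year_mean = tp$year_mean %||% 2005,
      year_sd = tp$year_sd %||% 8,
      prop_female = mk_pf(tp$prop_female),
      retraction_rate = tp$retraction_rate %||% 0.01,
      weight = tp$weight %||% 1
    )
  })
  synthetic_config(
    n_papers = cfg$n_papers,
    topics = topics,
    cluster_separation = cfg$cluster_separation %||% 6,
    dim = cfg$dim %||% 50,
    seed = cfg$seed %||% 1,
    year_range = year_range
  )
}

# Draw a forename consistent with a Bernoulli(prop_female) gender draw,
# using names that are strongly gendered in the lookup table at that year.
draw_forename <- function(table, year, female) {
  ent <- table$entries
  yr <- max(table$year_range[1], min(table$year_range[2], year))
  covered <- sort(unique(ent$year))
  yr <- covered[which.min(abs(covered - yr))]
  sub <- ent[ent$year == yr, , drop = FALSE]
  pool <- if (female) sub$name[sub$prop_female >= 0.85] else
    sub$name[sub$prop_female <= 0.15]
  if (length(pool) == 0) pool <- sub$name
  pool[sample.int(length(pool), 1)]
}

#' Generate a synthetic bibliographic corpus
#'
#' Emits one row per paper with a topic-specific abstract (a per-topic
#' multinomial over the topic vocabulary mixed with shared stop-words), a
#' journal title carrying the topic's keyword, a publication year from the
#' topic's Gaussian drift distribution, first/last author forenames drawn
#' from the name table according to the topic's female-proportion-by-year
#' function, and a retraction flag drawn at the topic's rate. Identical
#' config and seed give byte-identical corpora.
#'
#' @param config a [synthetic_config()].
#' @return a data.frame of class `paper_records` with columns `pmid`,
#'   `title`, `abstract`, `journal`, `year`, `language`, `first_forename`,
#'   `last_forename`, `retracted` and the ground-truth `topic`.
#' @export
generate_records <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_papers
  empty <- data.frame(
    pmid = character(0), title = character(0), abstract = character(0),
    journal = character(0), year = integer(0), language = character(0),
    first_forename = character(0), last_forename = character(0),
    retracted = logical(0), topic = character(0),
    stringsAsFactors = FALSE
  )
  class(empty) <- c("paper_records", "data.frame")
  if (n == 0) return(empty)

  seeds <- child_seeds(config$seed, 2)
  topics <- config$topics
  weights <- vapply(topics, `[[`, numeric(1), "weight")
  stops <- stopword_pool()
  templates <- c("Journal of %s Research", "Annals of %s",
                 "International %s Reports", "Archives of Clinical %s",
                 "%s Letters")

  with_seed(seeds[1], {
    topic_idx <- sample.int(length(topics), n, replace = TRUE,
                            prob = weights)
    year_mu <- vapply(topics, `[[`, numeric(1), "year_mean")[topic_idx]
    year_sd <- vapply(topics, `[[`, numeric(1), "year_sd")[topic_idx]
    year <- as.integer(round(rnorm(n, year_mu, year_sd)))
    year <- pmax(config$year_range[1], pmin(config$year_range[2], year))

    abstract <- character(n)
    title <- character(n)
    journal <- character(n)
    first_forename <- character(n)
    last_forename <- character(n)
    retracted <- logical(n)

    for (i in seq_len(n)) {
      tp <- topics[[topic_idx[i]]]
      draw_words <- function(m) {
        from_topic <- runif(m) < 0.55
        w <- character(m)
        w[from_topic] <- sample(tp$vocabulary, sum(from_topic),
                                replace = TRUE, prob = tp$vocab_weights)
        w[!from_topic] <- sample(stops, sum(!from_topic), replace = TRUE)
        w
      }
      txt <- paste(draw_words(45), collapse = " ")
      while (nchar(txt) < config$min_chars - 1) {
        txt <- paste(txt, paste(draw_words(15), collapse = " "))
      }
      if (nchar(txt) > config$max_chars - 1) {
        txt <- substr(txt, 1, config$max_chars - 1)
        txt <- sub("\\s+\\S*$", "", txt)
      }
      abstract[i] <- paste0(txt, ".")

      tw <- sample(tp$vocabulary, 4, prob = tp$vocab_weights,
                   replace = length(tp$vocabulary) < 4)
      title[i] <- paste0(toupper(substring(tw[1], 1, 1)),
                         substring(tw[1], 2), " ",
                         paste(tw[-1], collapse = " "))

      kw <- tp$journal_keyword
      kw_cap <- paste0(toupper(substring(kw, 1, 1)), substring(kw, 2))
      journal[i] <- sprintf(sample(templates, 1), kw_cap)

      pf <- tp$prop_female(year[i])
      first_forename[i] <- draw_forename(config$name_table, year[i],
                                         runif(1) < pf)
      last_forename[i] <- draw_forename(config$name_table, year[i],
                                        runif(1) < pf)
      retracted[i] <- runif(1) < tp$retraction_rate
    }

    topic_names <- vapply(topics, `[[`, character(1), "name")
    out <- data.frame(
      pmid = sprintf("%07d", seq_len(n)),
      title = title, abstract = abstract, journal = journal,
      year = year, language = "eng",
      first_forename = first_forename, last_forename = last_forename,
      retracted = retracted, topic = topic_names[topic_idx],
      stringsAsFactors = FALSE
    )
    class(out) <- c("paper_records", "data.frame")
    out
  })
}

#' Generate labelled Gaussian-mixture vectors
#'
#' Draws rows from spherical unit-variance Gaussians whose centres are
#' pairwise `cluster_separation` apart (in within-cluster s.d. units).
#' Centres are the vertices of a regular simplex, which requires
#' `dim >= n_topics - 1` for exact pairwise distances; in lower dimensions
#' centres are placed on a sphere of the matching radius and distances are
#' approximate.
#'
#' @param config a [synthetic_config()].
#' @return list with `vectors` (a [vector_set()]) and `labels` (character,
#'   one topic name per row).
#' @export
generate_vector_mixture <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_topics <- length(config$topics)
  if (n_topics < 1) stop("need at least one topic", call. = FALSE)
  if (config$dim < 2) stop("`dim` must be >= 2", call. = FALSE)
  n <- config$n_papers
  d <- config$dim
  sep <- config$cluster_separation

  # Regular simplex with unit pairwise distances, then scaled by sep.
  centers <- diag(n_topics) - 1 / n_topics
  sv <- svd(centers)
  coords <- sv$u %*% diag(sv$d, n_topics)      # pairwise distance sqrt(2)
  coords <- coords[, seq_len(min(n_topics - 1, d)), drop = FALSE] / sqrt(2)
  C <- matrix(0, n_topics, d)
  C[, seq_len(ncol(coords))] <- coords
  C <- C * sep

  seeds <- child_seeds(config$seed, 3)
  weights <- vapply(config$topics, `[[`, numeric(1), "weight")
  topic_names <- vapply(config$topics, `[[`, character(1), "name")
  with_seed(seeds[2], {
    idx <- sample.int(n_topics, n, replace = TRUE, prob = weights)
    X <- matrix(rnorm(n * d), n, d) + C[idx, , drop = FALSE]
    list(
      vectors = vector_set(ids = sprintf("%07d", seq_len(n)), X = X,
                           metric = "euclidean", provenance = "synthetic"),
      labels = topic_names[idx]
    )
  })
}
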