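# Deterministic synthetic corpora for offline testing of every pipeline
# stage. One spec-derived plan drives all four source formats, so the same
# drug universe appears (with per-source coverage gaps, multi-version
# documents, one-to-many and missing identifier mappings) in SPL XML,
# plain-text labels, a DrugBank-style datafile and an Orange Book products
# file, together with a ground-truth manifest for round-trip testing.
# Generation is template-based, never statistical: ground truth must be
# exact and auditable.

#' Specification for a synthetic labeling corpus
#'
#' @param n_drugs Number of drugs in the universe. Default 60.
#' @param seed Integer seed (mandatory; all generation is a pure function
#'   of the spec including the seed).
#' @param p_dailymed,p_drugs_at_fda,p_drugbank Probability that each source
#'   covers a given drug.
#' @param section_presence Named probabilities that a coverable section is
#'   present in a given document; defaults chosen to leave realistic gaps.
#' @param max_versions Maximum number of SPL versions per drug (versions
#'   share a Set ID and carry increasing effective dates).
#' @param p_multi_app Probability a drug's documents list a second FDA
#'   application number (one-to-many mapping).
#' @param p_unmapped Probability an SPL document carries no application
#'   number (unmapped), and that a DrugBank drug lists none.
#' @param noise_rate Rate of PDF-conversion-style noise (stray line breaks,
#'   repeated page headers) injected into the free-text labels. Default 0.
#' @param n_anda_rows Number of ANDA product rows in the Orange Book file
#'   (excluded from the NDA reference set).
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_drugs = 60L, seed = 1L,
                        p_dailymed = 0.85, p_drugs_at_fda = 0.85,
                        p_drugbank = 0.8,
                        section_presence = NULL,
                        max_versions = 3L,
                        p_multi_app = 0.15, p_unmapped = 0.08,
                        noise_rate = 0, n_anda_rows = 8L) {
  default_presence <- c(
    boxed_warning = 0.5, indication = 0.9, dosage_admin = 0.85,
    pregnancy = 0.7, lactation = 0.6, mechanism_of_action = 0.8,
    pharmacodynamics = 0.75, absorption = 0.85, distribution = 0.7,
    metabolism = 0.75, excretion = 0.7, food_effect = 0.5
  )
  if (!is.null(section_presence)) {
    default_presence[names(section_presence)] <- section_presence
  }
  stopifnot(
    n_drugs >= 1, all(default_presence >= 0 & default_presence <= 1),
    noise_rate >= 0 && noise_rate <= 1
  )
  structure(
    list(
      n_drugs = as.integer(n_drugs), seed = as.integer(seed),
      p_dailymed = p_dailymed, p_drugs_at_fda = p_drugs_at_fda,
      p_drugbank = p_drugbank,
      section_presence = default_presence,
      max_versions = as.integer(max_versions),
      p_multi_app = p_multi_app, p_unmapped = p_unmapped,
      noise_rate = noise_rate, n_anda_rows = as.integer(n_anda_rows)
    ),
    class = "corpus_spec"
  )
}

# ---- paragraph templates ---------------------------------------------------

# Each template carries an exact ground-truth label. The adversarial
# templates are modeled on the two archetypal failure modes of keyword
# rules: negative boilerplate that contains the food-effect phrase
# ("methadone" archetype, a rule false positive) and genuine meal-effect
# content that never uses the word "food" ("naloxegol" archetype, a rule
# false negative). Non-adversarial positives always contain a rule-1
# phrase; non-adversarial negatives never contain the substring "food".
fe_templates <- function() {
  list(
    pos = c(
      "The effect of food on {drug} was evaluated in {n} healthy subjects; administration with a high-fat meal increased AUC by {p} percent and Cmax by {q} percent.",
      "Food effect studies showed that coadministration of {drug} with a high-fat meal delayed median Tmax by approximately {h} hours without a clinically meaningful change in AUC.",
      "When {drug} was taken with food, the rate of absorption decreased and Cmax was reduced by {p} percent; the effects of food on overall exposure were not clinically significant.",
      "A food effect assessment of {drug} demonstrated that a high-fat meal reduced Cmax by {p} percent relative to the fasted state, while AUC remained unchanged."
    ),
    pos_adv = c(
      "A high-fat meal increased the extent and rate of {drug} absorption. The Cmax and AUC were increased by approximately {p} and {q} percent, respectively. In clinical trials, {drug} was dosed on an empty stomach approximately 1 h prior to the first meal in the morning.",
      "Administration of {drug} with a high-fat breakfast decreased Cmax by {p} percent and delayed median Tmax by about {h} hours; dosing on an empty stomach is recommended."
    ),
    neg = c(
      "The absolute oral bioavailability of {drug} is approximately {p} percent, with peak plasma concentrations reached {h} hours after dosing.",
      "{drug} is rapidly absorbed after oral administration; median Tmax is about {h} hours and exposure is dose proportional over the {a} to {b} mg range.",
      "Following repeated once-daily dosing of {drug}, steady state is reached within {h} days with minimal accumulation.",
      "Plasma protein binding of {drug} is approximately {p} percent and absorption is not saturable at therapeutic doses."
    ),
    neg_adv = c(
      "Effect of food on the bioavailability of {drug} has not been evaluated.",
      "The effect of food on the absorption of {drug} has not been studied in clinical trials."
    )
  )
}

fill_template <- function(tmpl, drug) {
  vals <- c(
    drug = drug,
    n = sample(12:48, 1),
    p = sample(10:60, 1),
    q = sample(10:60, 1),
    h = sample(1:6, 1),
    a = sample(c(5L, 10L, 25L), 1),
    b = sample(c(50L, 100L, 200L), 1)
  )
  for (k in names(vals)) {
    tmpl <- gsub(paste0("{", k, "}"), vals[[k]], tmpl, fixed = TRUE)
  }
  tmpl
}

make_drug_names <- function(n) {
  syl <- c(
    "al", "bex", "cor", "dal", "fex", "gri", "hal", "lym", "mor", "nex",
    "pra", "quo", "ril", "san", "tor", "vex", "zan", "domi", "lute", "pax"
  )
  vapply(seq_len(n), function(i) {
    nm <- paste0(
      sample(syl, 1), sample(syl, 1), sample(syl, 1), sample(c("in", "ol", "ide", "ate"), 1)
    )
    paste0(toupper(substr(nm, 1, 1)), substr(nm, 2, nchar(nm)))
  }, character(1))
}

#' Generate labeled food-effect paragraphs
#'
#' Draws `n_pos` food-effect and `n_neg` non-food-effect paragraphs from
#' the template sets with lexical variation; `adversarial_fraction` of each
#' class comes from the adversarial templates (`naloxegol` archetype for
#' positives - meal-effect content without the keyword "food" - and
#' `methadone` archetype for negatives - not-evaluated boilerplate that
#' contains the food-effect phrase). By construction both rule-based
#' baselines are correct exactly on the non-adversarial rows. Sources
#' alternate deterministically so the per-source pools are balanced.
#'
#' @param n_pos,n_neg Class counts.
#' @param adversarial_fraction In \[0, 1\]. Default 0.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @return Labeled-paragraph tibble with extra columns `adversarial`
#'   (logical) and `archetype` (`"methadone"`, `"naloxegol"` or `NA`).
#' @export
generate_foodeffect_paragraphs <- function(n_pos, n_neg,
                                           adversarial_fraction = 0,
                                           seed = 1L) {
  stopifnot(
    adversarial_fraction >= 0, adversarial_fraction <= 1,
    n_pos >= 0, n_neg >= 0, n_pos + n_neg > 0
  )
  tpl <- fe_templates()
  withr::with_seed(seed, {
    drugs <- make_drug_names(max(50L, ceiling((n_pos + n_neg) / 4)))
    make_rows <- function(n, pool, label, adversarial, archetype) {
      if (n == 0) {
        return(NULL)
      }
      tibble::tibble(
        text = vapply(seq_len(n), function(i) {
          fill_template(sample(pool, 1), sample(drugs, 1))
        }, character(1)),
        label = label,
        adversarial = adversarial,
        archetype = archetype
      )
    }
    n_adv_pos <- round(n_pos * adversarial_fraction)
    n_adv_neg <- round(n_neg * adversarial_fraction)
    rows <- dplyr::bind_rows(
      make_rows(n_pos - n_adv_pos, tpl$pos, "food_effect", FALSE, NA_character_),
      make_rows(n_adv_pos, tpl$pos_adv, "food_effect", TRUE, "naloxegol"),
      make_rows(n_neg - n_adv_neg, tpl$neg, "non_food_effect", FALSE, NA_character_),
      make_rows(n_adv_neg, tpl$neg_adv, "non_food_effect", TRUE, "methadone")
    )
    rows <- rows[sample(nrow(rows)), , drop = FALSE]
    rows$source <- rep(c("dailymed", "drugs_at_fda"), length.out = nrow(rows))
    rows$doc_ref <- sprintf("synpara-%05d", seq_len(nrow(rows)))
    rows$annotation_method <- "manual"
    rows[, c(
      "text", "label", "source", "doc_ref", "annotation_method",
      "adversarial", "archetype"
    )]
  })
}

#' Embed labeled paragraphs into a synthetic absorption section
#'
#' Builds a document whose absorption section contains the given
#' paragraphs in order, planting the typographic cues the regex annotator
#' relies on: non-adversarial food-effect paragraphs get a standalone
#' subtitle line or a "Effect of Food:"-style prefix (alternating), while
#' adversarial food-effect paragraphs are embedded bare - exactly the case
#' where subtitle detection cannot see them. Non-food-effect paragraphs
#' are embedded bare.
#'
#' @param paragraphs Tibble from [generate_foodeffect_paragraphs()].
#' @param native_id,source Document identity.
#' @return A one-row documents tibble.
#' @export
as_absorption_document <- function(paragraphs,
                                   native_id = "synthetic-absorption",
                                   source = "dailymed") {
  parts <- character()
  k <- 0L
  for (i in seq_len(nrow(paragraphs))) {
    txt <- paragraphs$text[i]
    cued <- paragraphs$label[i] == "food_effect" && !paragraphs$adversarial[i]
    if (cued) {
      k <- k + 1L
      if (k %% 2L == 1L) {
        parts <- c(parts, "Food Effect", txt)
      } else {
        parts <- c(parts, paste0("Effect of Food: ", txt))
      }
    } else {
      parts <- c(parts, txt)
    }
  }
  label_document(
    source = source, native_id = native_id,
    sections = c(absorption = paste(parts, collapse = "\n\n"))
  )
}

# ---- drug universe plan ----------------------------------------------------

spl_display_name <- function(kind) {
  c(
    boxed_warning = "Boxed Warning", indication = "Indications and Usage",
    dosage_admin = "Dosage and Administration", pregnancy = "Pregnancy",
    lactation = "Lactation", mechanism_of_action = "Mechanism of Action",
    pharmacodynamics = "Pharmacodynamics",
    pharmacokinetics = "Pharmacokinetics", absorption = "Absorption",
    distribution = "Distribution", metabolism = "Metabolism",
    excretion = "Excretion", food_effect = "Food Effect"
  )[[kind]]
}

generic_section_text <- function(kind, drug) {
  sprintf(
    "%s narrative for %s: clinical statement %d relevant to prescribers. Supplementary remark %d supporting the assessment.",
    spl_display_name(kind), drug, sample(1:99, 1), sample(1:99, 1)
  )
}

make_set_ids <- function(n) {
  hexes <- function(k) {
    vapply(seq_len(n), function(i) {
      paste(sample(c(0:9, letters[1:6]), k, replace = TRUE), collapse = "")
    }, character(1))
  }
  paste(hexes(8), hexes(4), hexes(4), hexes(4), hexes(12), sep = "-")
}

# Builds the per-(drug, source) section maps: a `render` map whose
# pharmacokinetics entry is the assembled subtitled block, and the
# `expected` map a parser should recover after subsection splitting.
plan_sections <- function(drug, idx, presence, capable_kinds,
                          version_tag = NULL) {
  top <- c(
    "boxed_warning", "indication", "dosage_admin", "pregnancy", "lactation",
    "mechanism_of_action", "pharmacodynamics"
  )
  admef <- pk_subsections()
  tag <- function(x) if (is.null(version_tag)) x else paste0(x, " ", version_tag)
  render <- character()
  expected <- character()
  for (kind in intersect(top, capable_kinds)) {
    if (stats::runif(1) < presence[[kind]]) {
      txt <- tag(generic_section_text(kind, drug))
      render[[kind]] <- txt
      expected[[kind]] <- txt
    }
  }
  pk_parts <- character()
  preamble <- if (stats::runif(1) < 0.5) {
    tag(sprintf(
      "General pharmacokinetic profile of %s: exposure parameters summarized below item %d.",
      drug, sample(1:99, 1)
    ))
  }
  if (!is.null(preamble)) {
    pk_parts <- c(pk_parts, preamble)
    expected[["pharmacokinetics"]] <- preamble
  }
  i <- 0L
  for (kind in intersect(admef, capable_kinds)) {
    if (stats::runif(1) >= presence[[kind]]) next
    i <- i + 1L
    txt <- if (kind == "absorption") {
      tag(fill_template(sample(fe_templates()$neg, 1), drug))
    } else if (kind == "food_effect") {
      tag(fill_template(sample(fe_templates()$pos, 1), drug))
    } else {
      tag(generic_section_text(kind, drug))
    }
    title <- spl_display_name(kind)
    if ((idx + i) %% 2L == 0L) {
      pk_parts <- c(pk_parts, paste0(title, ":"), txt)
    } else {
      pk_parts <- c(pk_parts, paste0(title, ": ", txt))
    }
    expected[[kind]] <- txt
  }
  if (length(pk_parts)) {
    render[["pharmacokinetics"]] <- paste(pk_parts, collapse = "\n\n")
  }
  list(render = render, expected = expected)
}

#' Build the deterministic generation plan behind a corpus spec
#'
#' All randomness in corpus generation is consumed here, under the spec's
#' seed, so the four format generators (and their manifests) describe one
#' consistent drug universe and repeated runs are byte-identical.
#'
#' @param spec A [corpus_spec()].
#' @return A list with elements `drugs`, `spl`, `freetext`, `drugbank`,
#'   `orange_book` (row tibble) and `reference` (the planted NDA numbers).
#' @export
corpus_plan <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_drugs
    nums <- sample(100000:999999, n + n + spec$n_anda_rows + 3L)
    app <- sprintf("%06d", nums[seq_len(n)])
    extra_pool <- sprintf("%06d", nums[n + seq_len(n)])
    anda_nums <- sprintf("%06d", nums[2L * n + seq_len(spec$n_anda_rows)])
    ob_only <- sprintf("%06d", nums[2L * n + spec$n_anda_rows + 1:3])
    drugs <- tibble::tibble(
      idx = seq_len(n),
      app_number = app,
      drug_name = make_drug_names(n),
      set_id = make_set_ids(n),
      drugbank_id = sprintf("DB%05d", sample(1:99999, n)),
      extra_app = ifelse(stats::runif(n) < spec$p_multi_app,
        extra_pool, NA_character_
      ),
      in_dailymed = stats::runif(n) < spec$p_dailymed,
      in_drugs_at_fda = stats::runif(n) < spec$p_drugs_at_fda,
      in_drugbank = stats::runif(n) < spec$p_drugbank,
      unmapped_spl = stats::runif(n) < spec$p_unmapped,
      unmapped_db = stats::runif(n) < spec$p_unmapped,
      base_date = sample(
        seq(as.Date("2018-01-15"), as.Date("2020-11-30"), by = "day"), n,
        replace = TRUE
      ),
      n_versions = sample(seq_len(spec$max_versions), n, replace = TRUE)
    )
    # guarantee the branch-coverage cases regardless of the draws
    if (n >= 4L) {
      drugs$in_dailymed[1:4] <- TRUE
      drugs$in_drugs_at_fda[1:4] <- TRUE
      drugs$in_drugbank[1:4] <- TRUE
      drugs$unmapped_spl[1] <- TRUE
      drugs$unmapped_spl[2:4] <- FALSE
      drugs$unmapped_db[2] <- TRUE
      drugs$unmapped_db[c(1, 3, 4)] <- FALSE
      drugs$extra_app[3] <- extra_pool[3]
      if (spec$max_versions >= 2L) drugs$n_versions[4] <- spec$max_versions
    }

    all_kinds <- section_kinds()
    db_kinds <- c(
      "indication", "mechanism_of_action", "pharmacodynamics",
      "absorption", "distribution", "metabolism", "excretion"
    )

    spl_rows <- list()
    for (i in which(drugs$in_dailymed)) {
      d <- drugs[i, ]
      secs <- plan_sections(d$drug_name, d$idx, spec$section_presence, all_kinds)
      for (v in seq_len(d$n_versions)) {
        vsec <- if (v == d$n_versions) {
          secs
        } else {
          plan_sections(d$drug_name, d$idx + v, spec$section_presence,
            all_kinds,
            version_tag = sprintf("[v%d]", v)
          )
        }
        app_numbers <- if (d$unmapped_spl) {
          character()
        } else {
          c(d$app_number, if (!is.na(d$extra_app)) d$extra_app)
        }
        spl_rows[[length(spl_rows) + 1L]] <- tibble::tibble(
          file = sprintf("%s_v%d.xml", d$set_id, v),
          set_id = d$set_id,
          version = v,
          effective_date = d$base_date + 90L * (v - 1L),
          app_numbers = list(app_numbers),
          render = list(vsec$render),
          sections = list(vsec$expected)
        )
      }
    }
    spl <- dplyr::bind_rows(spl_rows)

    ft_rows <- list()
    for (i in which(drugs$in_drugs_at_fda)) {
      d <- drugs[i, ]
      secs <- plan_sections(d$drug_name, d$idx + 101L, spec$section_presence,
        all_kinds
      )
      ft_rows[[length(ft_rows) + 1L]] <- tibble::tibble(
        file = sprintf("NDA%s_%s.txt", d$app_number,
          format(d$base_date, "%Y%m%d")
        ),
        app_number = d$app_number,
        effective_date = d$base_date,
        drug_name = d$drug_name,
        in_reference = TRUE,
        render = list(secs$render),
        sections = list(secs$expected),
        case_style = sample(c("upper", "title", "lower"), 1),
        outlined = stats::runif(1) < 0.5
      )
    }
    # a couple of ANDA-numbered labels that the reference restriction drops
    for (k in seq_len(min(2L, spec$n_anda_rows))) {
      nm <- make_drug_names(1)
      secs <- plan_sections(nm, 500L + k, spec$section_presence, all_kinds)
      ft_rows[[length(ft_rows) + 1L]] <- tibble::tibble(
        file = sprintf("ANDA%s_%s.txt", anda_nums[k], "20200301"),
        app_number = anda_nums[k],
        effective_date = as.Date("2020-03-01"),
        drug_name = nm,
        in_reference = FALSE,
        render = list(secs$render),
        sections = list(secs$expected),
        case_style = "upper",
        outlined = TRUE
      )
    }
    freetext <- dplyr::bind_rows(ft_rows)

    db_rows <- list()
    for (i in which(drugs$in_drugbank)) {
      d <- drugs[i, ]
      secs <- character()
      for (kind in db_kinds) {
        if (stats::runif(1) < spec$section_presence[[kind]]) {
          secs[[kind]] <- if (kind == "absorption") {
            fill_template(sample(fe_templates()$neg, 1), d$drug_name)
          } else {
            generic_section_text(kind, d$drug_name)
          }
        }
      }
      app_numbers <- if (d$unmapped_db) {
        character()
      } else {
        c(d$app_number, if (!is.na(d$extra_app)) d$extra_app)
      }
      db_rows[[length(db_rows) + 1L]] <- tibble::tibble(
        drugbank_id = d$drugbank_id,
        drug_name = d$drug_name,
        app_numbers = list(app_numbers),
        sections = list(secs)
      )
    }
    drugbank <- dplyr::bind_rows(db_rows)

    reference <- sort(unique(c(
      drugs$app_number, drugs$extra_app[!is.na(drugs$extra_app)], ob_only
    )))
    ob_rows <- dplyr::bind_rows(
      tibble::tibble(
        Appl_Type = "N", Appl_No = rep(drugs$app_number, 2L),
        Trade_Name = toupper(rep(drugs$drug_name, 2L)),
        Product_No = rep(c("001", "002"), each = spec$n_drugs)
      ),
      tibble::tibble(
        Appl_Type = "N",
        Appl_No = c(drugs$extra_app[!is.na(drugs$extra_app)], ob_only),
        Trade_Name = "COMBINATION",
        Product_No = "001"
      ),
      tibble::tibble(
        Appl_Type = "A", Appl_No = anda_nums,
        Trade_Name = "GENERIC", Product_No = "001"
      )
    )
    ob_rows <- ob_rows[sample(nrow(ob_rows)), , drop = FALSE]
    ob_rows <- dplyr::mutate(
      ob_rows,
      Ingredient = "SYNTHETIC INGREDIENT",
      `DF;Route` = "TABLET;ORAL",
      Applicant = "SYNTHLABS",
      Strength = "10MG",
      Approval_Date = "Jan 1, 2019",
      .before = "Appl_Type"
    )

    list(
      drugs = drugs, spl = spl, freetext = freetext, drugbank = drugbank,
      orange_book = ob_rows, reference = reference,
      noise_rate = spec$noise_rate, seed = spec$seed
    )
  })
}

# ---- file rendering --------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_spl_xml <- function(row) {
  loinc_by_kind <- setNames(names(loinc_section_map()), loinc_section_map())
  secs <- row$render[[1]]
  sec_xml <- vapply(names(secs), function(kind) {
    paras <- split_paragraphs(secs[[kind]])
    paste0(
      "    <component><section>\n",
      sprintf(
        "      <code code=\"%s\" codeSystem=\"2.16.840.1.113883.6.1\" displayName=\"%s SECTION\"/>\n",
        loinc_by_kind[[kind]], toupper(spl_display_name(kind))
      ),
      "      <text>\n",
      paste0("        <paragraph>", xml_escape(paras), "</paragraph>",
        collapse = "\n"
      ),
      "\n      </text>\n",
      "    </section></component>"
    )
  }, character(1))
  approvals <- vapply(row$app_numbers[[1]], function(a) {
    paste0(
      "    <approval><id extension=\"NDA", a,
      "\" root=\"2.16.840.1.113883.3.150\"/></approval>"
    )
  }, character(1))
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<document xmlns=\"urn:hl7-org:v3\">\n",
    sprintf("  <id root=\"%s\"/>\n", row$set_id),
    sprintf("  <setId root=\"%s\"/>\n", row$set_id),
    sprintf("  <versionNumber value=\"%d\"/>\n", row$version),
    sprintf(
      "  <effectiveTime value=\"%s\"/>\n",
      format(row$effective_date, "%Y%m%d")
    ),
    "  <author><assignedEntity>\n",
    paste0(approvals, collapse = "\n"),
    if (length(approvals)) "\n" else "",
    "  </assignedEntity></author>\n",
    "  <component><structuredBody>\n",
    paste0(sec_xml, collapse = "\n"),
    "\n  </structuredBody></component>\n",
    "</document>\n"
  )
}

#' Generate an SPL corpus from a spec
#'
#' Writes one well-formed SPL-style XML file per planted document (Set ID,
#' version number, effective date, LOINC-coded sections, approval elements
#' carrying application numbers, subtitled pharmacokinetics blocks) and
#' returns the ground-truth manifest for round-trip testing.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory (created if needed).
#' @param plan Optional precomputed [corpus_plan()] (so that one plan can
#'   drive several generators).
#' @return Manifest tibble: `file` (full path), `set_id`, `version`,
#'   `effective_date`, `app_numbers`, `sections` (expected post-parse
#'   section map).
#' @export
generate_spl_corpus <- function(spec, dir, plan = corpus_plan(spec)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- plan$spl
  for (i in seq_len(nrow(manifest))) {
    writeLines(render_spl_xml(manifest[i, ]),
      file.path(dir, manifest$file[i]),
      sep = "", useBytes = TRUE
    )
  }
  manifest$file <- file.path(dir, manifest$file)
  dplyr::select(manifest, -"render")
}

render_heading <- function(kind, case_style, outlined, n1, n2) {
  phrase <- spl_display_name(kind)
  h <- switch(case_style,
    upper = toupper(phrase),
    lower = tolower(phrase),
    phrase
  )
  if (outlined) paste0(n1, ".", n2, " ", h) else h
}

apply_text_noise <- function(lines, noise_rate, rng_offset) {
  if (noise_rate <= 0) {
    return(lines)
  }
  out <- character()
  for (ln in lines) {
    words <- strsplit(ln, " ", fixed = TRUE)[[1]]
    if (length(words) >= 7 && stats::runif(1) < noise_rate) {
      cut <- sample(3:(length(words) - 3), 1)
      out <- c(
        out, paste(words[1:cut], collapse = " "),
        paste(words[-(1:cut)], collapse = " ")
      )
    } else {
      out <- c(out, ln)
    }
    if (nzchar(ln) && stats::runif(1) < noise_rate / 4) {
      out <- c(out, sprintf("LABEL PAGE %d", sample(2:40, 1)))
    }
  }
  out
}

render_freetext <- function(row, noise_rate) {
  order_kinds <- c(
    "boxed_warning", "indication", "dosage_admin", "pregnancy", "lactation",
    "mechanism_of_action", "pharmacodynamics", "pharmacokinetics"
  )
  secs <- row$render[[1]]
  lines <- c(toupper(row$drug_name), "")
  n1 <- 0L
  for (kind in intersect(order_kinds, names(secs))) {
    n1 <- n1 + 1L
    lines <- c(
      lines,
      render_heading(kind, row$case_style, row$outlined, n1, sample(1:9, 1)),
      ""
    )
    body <- strsplit(secs[[kind]], "\n", fixed = TRUE)[[1]]
    body <- apply_text_noise(body, noise_rate, n1)
    lines <- c(lines, body, "")
  }
  paste(lines, collapse = "\n")
}

#' Generate plain-text Drugs@FDA-style labels from a spec
#'
#' Writes heading-structured `.txt` labels (configurable heading case and
#' outline numbering; optional PDF-conversion noise such as stray line
#' breaks and repeated page headers at `spec$noise_rate`), named by the
#' `NDAnnnnnn_YYYYMMDD.txt` convention, plus a couple of ANDA-numbered
#' labels that the reference restriction later drops.
#'
#' @inheritParams generate_spl_corpus
#' @return Manifest tibble: `file`, `app_number`, `effective_date`,
#'   `in_reference`, `sections` (expected noise-free extraction).
#' @export
generate_freetext_labels <- function(spec, dir, plan = corpus_plan(spec)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- plan$freetext
  withr::with_seed(plan$seed + 1L, {
    for (i in seq_len(nrow(manifest))) {
      writeLines(render_freetext(manifest[i, ], plan$noise_rate),
        file.path(dir, manifest$file[i]),
        useBytes = TRUE
      )
    }
  })
  manifest$file <- file.path(dir, manifest$file)
  dplyr::select(manifest, -"render", -"case_style", -"outlined")
}

render_drugbank_xml <- function(manifest) {
  kind_to_tag <- setNames(names(drugbank_field_map()), drugbank_field_map())
  drug_xml <- vapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    secs <- row$sections[[1]]
    fields <- vapply(names(secs), function(kind) {
      sprintf(
        "    <%s>%s</%s>",
        kind_to_tag[[kind]], xml_escape(secs[[kind]]), kind_to_tag[[kind]]
      )
    }, character(1))
    products <- vapply(row$app_numbers[[1]], function(a) {
      paste0(
        "      <product>\n",
        sprintf("        <name>%s</name>\n", toupper(row$drug_name)),
        sprintf("        <fda-application-number>NDA%s</fda-application-number>\n", a),
        "      </product>"
      )
    }, character(1))
    paste0(
      "  <drug type=\"small molecule\">\n",
      sprintf("    <drugbank-id primary=\"true\">%s</drugbank-id>\n", row$drugbank_id),
      sprintf("    <name>%s</name>\n", row$drug_name),
      paste0(fields, collapse = "\n"),
      if (length(fields)) "\n" else "",
      "    <products>\n",
      paste0(products, collapse = "\n"),
      if (length(products)) "\n" else "",
      "    </products>\n",
      "  </drug>"
    )
  }, character(1))
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<drugbank xmlns=\"http://www.drugbank.ca\">\n",
    paste0(drug_xml, collapse = "\n"),
    "\n</drugbank>\n"
  )
}

#' Generate a DrugBank-style XML datafile from a spec
#'
#' One file with repeated `<drug>` elements: DrugBank-IDs, the seven
#' mapped content fields, and product records carrying zero, one or two
#' FDA application numbers (exercising unmapped and one-to-many cases).
#'
#' @inheritParams generate_spl_corpus
#' @param path Output file path.
#' @return Manifest tibble: `drugbank_id`, `app_numbers`, `sections`, and
#'   the written `file`.
#' @export
generate_drugbank_xml <- function(spec, path, plan = corpus_plan(spec)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(render_drugbank_xml(plan$drugbank), path,
    sep = "", useBytes = TRUE
  )
  out <- plan$drugbank
  out$file <- path
  out
}

#' Generate an Orange Book-style products file from a spec
#'
#' Tilde-delimited products file with duplicate product rows per NDA
#' application, ANDA rows (excluded from the reference), and a few
#' NDA numbers with no labeling documents anywhere.
#'
#' @inheritParams generate_drugbank_xml
#' @return The planted reference: sorted character vector of NDA numbers.
#' @export
generate_orange_book <- function(spec, path, plan = corpus_plan(spec)) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_delim(plan$orange_book, path, delim = "~", progress = FALSE)
  plan$reference
}

#' Generate the full four-format synthetic corpus
#'
#' Writes the SPL directory, free-text directory, DrugBank XML and Orange
#' Book file under `dir`, plus a JSON ground-truth manifest.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory.
#' @return List with the four per-format manifests, the `reference`
#'   numbers, and the file/directory `paths`.
#' @export
generate_corpus <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plan <- corpus_plan(spec)
  paths <- list(
    spl_dir = file.path(dir, "spl"),
    freetext_dir = file.path(dir, "freetext"),
    drugbank_xml = file.path(dir, "drugbank.xml"),
    orange_book = file.path(dir, "orange_book.txt"),
    manifest = file.path(dir, "manifest.json")
  )
  spl <- generate_spl_corpus(spec, paths$spl_dir, plan = plan)
  freetext <- generate_freetext_labels(spec, paths$freetext_dir, plan = plan)
  drugbank <- generate_drugbank_xml(spec, paths$drugbank_xml, plan = plan)
  reference <- generate_orange_book(spec, paths$orange_book, plan = plan)
  jsonlite::write_json(
    list(
      reference = reference,
      spl = dplyr::mutate(spl, file = basename(.data$file)),
      freetext = dplyr::mutate(freetext, file = basename(.data$file)),
      drugbank = dplyr::select(drugbank, -"file")
    ),
    paths$manifest,
    auto_unbox = TRUE, null = "null", digits = NA
  )
  list(
    spl = spl, freetext = freetext, drugbank = drugbank,
    reference = reference, paths = paths
  )
}
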