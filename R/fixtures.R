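# Shipped questionnaire fixtures. The exact prompts and response options of
# the source instrument are not public; the schema below reconstructs all 36
# items (the 29 retained by the published six-factor solution plus the 7 it
# did not retain) with plausible scale kinds. Scale metadata is a fixture,
# not an assertion about the original instrument; the published pattern
# loadings and reliabilities are reproduced as printed.

likert4 <- c("No, never", "Yes, a few times", "Yes, most of the time",
             "Yes, all the time")
likert3_abuse <- c("Yes, more than once", "Yes, once", "No, never")
yn <- c("No", "Yes")

#' The shipped responsiveness & respectful-treatment questionnaire schema
#'
#' Thirty-six ordinal items on mixed scales (3- to 7-point Likert, binary,
#' categorical with non-scorable labels), with reverse-coding flags on the
#' negatively phrased mistreatment items and recode rules for merged
#' categories. Reconstructed: prompt wording and category labels are
#' plausible stand-ins, while item identity, factor membership and
#' loadings follow the published solution.
#'
#' @return An `rrt_schema` with 36 items.
#' @export
rrt_schema_fixture <- function() {
  L4 <- function(id, prompt, non_scored = character(), reverse = FALSE)
    item_definition(id, response_scale("likert", likert4, non_scored),
                    prompt = prompt, reverse = reverse)
  YN <- function(id, prompt, non_scored = character(), reverse = FALSE,
                 kind = "binary", labels = yn)
    item_definition(id, response_scale(kind, labels, non_scored),
                    prompt = prompt, reverse = reverse)
  items <- list(
    # -- communication & supportive care -----------------------------------
    L4("providers_introduced",
       "Did the providers introduce themselves to you with their names?"),
    L4("explained_done",
       "Did you feel the providers explained what had been done to you?"),
    YN("permission_vaginal_exam",
       "Did the provider ask permission before a vaginal examination?",
       non_scored = "Not relevant", kind = "categorical"),
    L4("explained_exams",
       "Did the provider explain why they were carrying out examinations?"),
    L4("explained_medicine",
       "Did the provider explain why they were giving you any medicine?",
       non_scored = "Not relevant"),
    L4("could_ask_questions",
       "Did you feel you could ask the provider any questions you had?"),
    L4("talked_feelings",
       "Did the provider talk to you about how you were feeling?"),
    L4("addressed_fears",
       "Did the provider address your anxieties and fears?"),
    YN("encouraged_walk",
       "Were you encouraged to walk around during labour?",
       non_scored = "I did not want to", kind = "categorical"),
    YN("encouraged_eat_drink",
       "Were you encouraged to eat and drink during labour?",
       non_scored = "I did not want to", kind = "categorical"),
    L4("paid_attention",
       "When you needed help, did you feel the providers paid attention?"),
    # -- hospital environment ----------------------------------------------
    item_definition("hospital_clean",
                    response_scale("likert",
                                   c("Very dirty", "Somewhat dirty",
                                     "Neither clean nor dirty",
                                     "Somewhat clean", "Very clean")),
                    prompt = "Would you say the hospital was clean?"),
    YN("clean_water",
       "Was there clean water in the hospital, e.g. for taking a shower?",
       non_scored = "Don't know", kind = "categorical"),
    YN("drinking_water",
       "Were you able to access clean drinking water when you needed it?",
       non_scored = "Don't know", kind = "categorical"),
    # -- maintained respect & dignity --------------------------------------
    L4("treated_respect",
       "Did the providers at the hospital treat you with respect?"),
    L4("treated_friendly",
       "Did the providers treat you in a friendly manner?"),
    item_definition("waiting_time",
                    response_scale("likert",
                                   c("Very long", "Somewhat long",
                                     "Acceptable", "Short", "Very short")),
                    prompt = paste("How would you describe the waiting time",
                                   "before admission to the labour ward?"),
                    reverse = TRUE),
    item_definition("shouted_at",
                    response_scale("likert", likert3_abuse),
                    prompt = "Were you shouted or screamed at by a provider?",
                    reverse = TRUE),
    item_definition("mocked",
                    response_scale("likert", likert3_abuse),
                    prompt = "Were you mocked at by a provider or staff?",
                    reverse = TRUE),
    L4("best_care",
       "Did you feel the providers took the best care of you they could?"),
    item_definition("recommend_hospital",
                    response_scale("likert",
                                   c("No", "Maybe", "Yes, definitely")),
                    prompt = paste("Would you recommend a family member to",
                                   "give birth in the same hospital?")),
    # -- social support ----------------------------------------------------
    YN("companion_labour",
       "Were you allowed someone you wanted to stay during labour?"),
    YN("companion_birth",
       "Were you allowed someone you wanted to stay during birth?"),
    # -- maintained privacy & confidentiality ------------------------------
    item_definition("info_shared",
                    response_scale("likert",
                                   c("Strongly agree", "Agree", "Disagree",
                                     "Strongly disagree")),
                    prompt = paste("My private or personal information was",
                                   "shared without my consent"),
                    reverse = TRUE),
    item_definition("privacy_violated",
                    response_scale("likert",
                                   c("Strongly agree", "Agree", "Disagree",
                                     "Strongly disagree")),
                    prompt = "My physical privacy was violated",
                    reverse = TRUE),
    # -- lack of physical & verbal abuse -----------------------------------
    YN("slapped_pinched",
       "Were you slapped or pinched by a provider?", reverse = TRUE),
    YN("negative_comments",
       "Did a provider make any negative comments about you?",
       reverse = TRUE),
    YN("shouted_items",
       "Were you shouted at because you did not bring items with you?",
       reverse = TRUE),
    YN("asked_bribe",
       "Did any staff suggest or ask you for a bribe or informal payment?",
       non_scored = c("Don't know", "Don't want to say"),
       kind = "categorical", reverse = TRUE),
    # -- items outside the published solution ------------------------------
    L4("called_by_name", "Did the providers call you by your name?"),
    YN("fundal_pressure",
       "Was forceful downward pressure placed on your abdomen?",
       non_scored = "Don't know", kind = "categorical", reverse = TRUE),
    L4("position_choice",
       "Were you able to be in the birth position of your choice?",
       non_scored = "Not relevant"),
    item_definition("helped_pain",
                    response_scale("likert",
                                   c("No", "Yes, partially",
                                     "Yes, completely",
                                     "I did not need any treatment for pain")),
                    prompt = "Did you feel providers helped you with your pain?",
                    recode = recode_rule("helped_pain", c(
                      "No" = "No",
                      "Yes, partially" = "Yes, partially",
                      "Yes, completely" = "Yes, completely",
                      "I experienced pain, but I was not distressed and did not need any treatment" =
                        "I did not need any treatment for pain",
                      "I did not experience any pain" =
                        "I did not need any treatment for pain"))),
    item_definition("felt_safe",
                    response_scale("likert",
                                   c("Not at all safe", "Very unsafe",
                                     "Somewhat unsafe", "Neutral",
                                     "Somewhat safe", "Safe", "Very safe")),
                    prompt = "In general, did you feel safe in the hospital?"),
    item_definition("held_down",
                    response_scale("binary", yn),
                    prompt = "Were you held down to the bed forcefully?",
                    reverse = TRUE,
                    recode = recode_rule("held_down", c(
                      "No" = "No", "Yes" = "Yes", "Don't know" = ".median"))),
    L4("language_understood",
       "Did the provider speak to you in a language you could understand?")
  )
  questionnaire_schema(items, version = "1.0")
}

#' The published six-factor pattern-loading fixture
#'
#' The accepted exploratory solution: 29 items on six factors, signed
#' pattern loadings as printed, including the single negative loading of
#' the informal-payment item, plus the published omega reliabilities.
#'
#' @return An `rrt_factors` object.
#' @export
rrt_factors_fixture <- function() {
  factor_spec(
    list(
      "Communication & supportive care" = c(
        providers_introduced = 0.55, explained_done = 0.82,
        permission_vaginal_exam = 0.82, explained_exams = 0.86,
        explained_medicine = 0.84, could_ask_questions = 0.66,
        talked_feelings = 0.78, addressed_fears = 0.51,
        encouraged_walk = 0.53, encouraged_eat_drink = 0.50,
        paid_attention = 0.55),
      "Hospital environment" = c(
        hospital_clean = 0.54, clean_water = 0.88, drinking_water = 0.91),
      "Maintained respect & dignity" = c(
        treated_respect = 0.45, treated_friendly = 0.45,
        waiting_time = 0.53, shouted_at = 0.83, mocked = 1.09,
        best_care = 0.46, recommend_hospital = 0.45),
      "Social support" = c(
        companion_labour = 0.85, companion_birth = 0.94),
      "Maintained privacy & confidentiality" = c(
        info_shared = 1.02, privacy_violated = 0.67),
      "Lack of physical & verbal abuse" = c(
        slapped_pinched = 0.40, negative_comments = 0.66,
        shouted_items = 0.78, asked_bribe = -0.73)),
    omegas = c("Communication & supportive care" = 0.916,
               "Hospital environment" = 0.735,
               "Maintained respect & dignity" = 0.814,
               "Social support" = 0.702,
               "Maintained privacy & confidentiality" = 0.710,
               "Lack of physical & verbal abuse" = 0.678),
    version = "1.0")
}

#' The responsiveness / respectful-treatment domain grouping fixture
#'
#' @return An `rrt_domains` object: communication & supportive care,
#'   hospital environment and social support form the responsiveness
#'   domain; respect & dignity, privacy & confidentiality and lack of
#'   physical & verbal abuse form the respectful-treatment domain.
#' @export
rrt_domains_fixture <- function() {
  domain_grouping(
    responsiveness = c("Communication & supportive care",
                       "Hospital environment", "Social support"),
    respectful = c("Maintained respect & dignity",
                   "Maintained privacy & confidentiality",
                   "Lack of physical & verbal abuse"))
}

#' Path to a shipped fixture file
#'
#' @param name One of `"schema"`, `"factors"`, `"domains"`.
#' @return Path to the YAML file under the package's `extdata`.
#' @export
rrt_fixture_path <- function(name = c("schema", "factors", "domains")) {
  name <- match.arg(name)
  fn <- c(schema = "rrt_schema.yaml", factors = "rrt_factors.yaml",
          domains = "rrt_domains.yaml")[[name]]
  path <- system.file("extdata", fn, package = "rrtscore")
  if (!nzchar(path)) stop("fixture not installed: ", fn, call. = FALSE)
  path
}
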