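Package: roboaffect
Title: Physiology-Driven Robot Facial Expression Selection and Preference
    Personalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for estimating a user's emotional state from wearable
    biosignals and driving a robot's facial expression from it. Heart rate
    variability (pNN50 over R-R intervals) provides a valence proxy and the
    difference of EEG Attention and Meditation indices an arousal proxy; the
    two are merged on a 1 Hz clock, mapped onto Russell's circumplex model to
    yield a four-quadrant emotion label with a five-level intensity updated
    cumulatively every 2.5 s, and converted into symbolic expression commands
    under synchronized, inversely synchronized, funny, and personalized
    policies. Individual expression preferences are learned from like/dislike
    click feedback with a logistic regression on (arousal, valence), evaluated
    by confusion-matrix accuracy, summarized into five preference groups, and
    tested for click-condition association with Pearson's chi-square.
    Includes a synthetic session generator with controllable pNN50, arousal,
    and ground-truth preference structure for end-to-end testing without
    sensor hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
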