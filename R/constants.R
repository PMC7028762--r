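# reporting-category constants shared across the costing functions

# direct-amount category labels accepted as service_item values
DIRECT_CATEGORIES <- c(medication      = "Medication",
                       complementary   = "Complementary care",
                       other_contacts  = "Other contacts")

COUNSELING_ITEM <- "counseling_outreach_clinic"
COUNSELING_CATEGORY <- "Counseling at the outreach clinic"
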