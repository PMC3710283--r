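# Default categorization ruleset: eleven food-outlet categories assigned
# from 4-character industry classification code prefixes plus whole-token
# name keywords (generic terms and common Quebec/Canada brand names).
# Priority runs most-specific first; a record claimed by a rule is never
# offered to a later rule. Records no rule claims fall back to a default
# category for their primary code. Fully user-overridable: point
# read_ruleset() at your own copy.

categories:
  - mega_markets
  - chain_supermarkets
  - grocery_stores
  - convenience_stores
  - bakery_shops
  - fruit_and_vegetable_stores
  - specialty_markets
  - natural_food_stores
  - fast_food_restaurants
  - full_service_restaurants
  - cafes

# food retail (5411 grocery, 5421 meat & fish, 5431 fruit & vegetable,
# 5441 candy & confectionery, 5451 dairy, 5461 retail bakeries,
# 5499 miscellaneous food), eating places 5812, drinking places 5813
scope_codes:
  - "5411"
  - "5421"
  - "5431"
  - "5441"
  - "5451"
  - "5461"
  - "5499"
  - "5812"
  - "5813"

exclusions:
  keywords: [bar, bars, tavern, taverne, pub, liquor, liquors, saq,
             caterer, caterers, catering, traiteur]

rules:
  - category: mega_markets
    priority: 1
    code_prefixes: ["54"]
    include_keywords: [costco, "club price", walmart, "wal mart",
                       "super c", maxi, hypermarche]
  - category: chain_supermarkets
    priority: 2
    code_prefixes: ["54"]
    include_keywords: [provigo, metro, iga, loblaws, supermarche,
                       supermarket, "super marche"]
  - category: natural_food_stores
    priority: 3
    code_prefixes: ["54"]
    include_keywords: [natural, naturel, naturelle, organic, biologique,
                       "health food", "aliments naturels", rachelle bery]
  - category: fruit_and_vegetable_stores
    priority: 4
    code_prefixes: ["5431"]
    include_keywords: [fruit, fruits, vegetable, vegetables, legume,
                       legumes, fruiterie, primeur]
  - category: specialty_markets
    priority: 5
    code_prefixes: ["5421", "5441", "5451", "5499"]
    include_keywords: [butcher, boucherie, poissonnerie, "fish market",
                       fromagerie, cheese, charcuterie, delicatessen, deli,
                       epices, spices, chocolat, chocolate, confiserie]
  - category: bakery_shops
    priority: 6
    code_prefixes: ["5461"]
    include_keywords: [bakery, boulangerie, patisserie, pastry, pain,
                       viennoiserie]
  - category: convenience_stores
    priority: 7
    code_prefixes: ["54"]
    include_keywords: [convenience, convenient, depanneur, "gas station",
                       station service, bonisoir, "couche tard", boni soir,
                       proxi, voisin, "7 jours"]
  - category: grocery_stores
    priority: 8
    code_prefixes: ["5411"]
    include_keywords: [grocery, epicerie, marche, alimentation, aliments]
  - category: fast_food_restaurants
    priority: 9
    code_prefixes: ["5812"]
    include_keywords: ["fast food", mcdonald, mcdonalds, "burger king",
                       subway, "pizza pizza", poutine, "la belle province",
                       valentine, kfc, pfk, wendy, "harvey s", "take out",
                       "a w"]
  - category: cafes
    priority: 10
    code_prefixes: ["5812", "5813"]
    include_keywords: [cafe, coffee, espresso, "tim hortons", starbucks,
                       "second cup", "van houtte", the, tea, "salon de the"]
  - category: full_service_restaurants
    priority: 11
    code_prefixes: ["5812"]
    include_keywords: [restaurant, resto, bistro, brasserie, grill,
                       steakhouse, trattoria, sushi]

# pool remnants: default category per primary (first) code
fallbacks:
  "5411": grocery_stores
  "5421": specialty_markets
  "5431": fruit_and_vegetable_stores
  "5441": specialty_markets
  "5451": specialty_markets
  "5461": bakery_shops
  "5499": specialty_markets
  "5812": full_service_restaurants
  "5813": cafes
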