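commodity_code,commodity_name,display_aggregate,group
2511,Wheat and products,wheat,starchy_staples
2805,Rice and products,rice,starchy_staples
2513,Barley and products,other cereals,starchy_staples
2514,Maize and products,maize,starchy_staples
2515,Rye and products,other cereals,starchy_staples
2516,Oats,other cereals,starchy_staples
2517,Millet and products,other cereals,starchy_staples
2518,Sorghum and products,other cereals,starchy_staples
2520,"Cereals, Other",other cereals,starchy_staples
2531,Potatoes and products,potatoes,starchy_staples
2532,Cassava and products,cassava,starchy_staples
2533,Sweet potatoes,other roots,starchy_staples
2534,"Roots, Other",other roots,starchy_staples
2535,Yams,other roots,starchy_staples
2615,Plantains,plantains,starchy_staples
2611,"Oranges, Mandarines",citrus,fruits
2612,"Lemons, Limes and products",citrus,fruits
2613,Grapefruit and products,citrus,fruits
2614,"Citrus, Other",citrus,fruits
2616,Bananas,bananas,fruits
2617,Apples and products,apples,fruits
2618,Pineapples and products,other fruits,fruits
2619,Dates,other fruits,fruits
2620,Grapes and products (excl wine),grapes,fruits
2625,"Fruits, other",other fruits,fruits
2601,Tomatoes and products,tomatoes,vegetables
2602,Onions,onions,vegetables
2605,"Vegetables, other",other vegetables,vegetables
2775,Aquatic Plants,other vegetables,vegetables
2731,Bovine Meat,beef,animal_source_foods
2732,Mutton & Goat Meat,mutton and goat,animal_source_foods
2733,Pigmeat,pork,animal_source_foods
2734,Poultry Meat,poultry,animal_source_foods
2735,"Meat, Other",other meat,animal_source_foods
2736,"Offals, Edible",other meat,animal_source_foods
2744,Eggs,eggs,animal_source_foods
2848,Milk - Excluding Butter,milk,animal_source_foods
2761,Freshwater Fish,freshwater fish,animal_source_foods
2762,Demersal Fish,other marine fish,animal_source_foods
2763,Pelagic Fish,other marine fish,animal_source_foods
2764,"Marine Fish, Other",other marine fish,animal_source_foods
2765,Crustaceans,other seafood,animal_source_foods
2766,Cephalopods,other seafood,animal_source_foods
2767,"Molluscs, Other",other seafood,animal_source_foods
2769,"Aquatic Animals, Others",other seafood,animal_source_foods
2546,Beans,beans,legumes_nuts_seeds
2547,Peas,other pulses and seeds,legumes_nuts_seeds
2549,"Pulses, Other and products",other pulses and seeds,legumes_nuts_seeds
2555,Soyabeans,soybeans,legumes_nuts_seeds
2556,Groundnuts,groundnuts,legumes_nuts_seeds
2557,Sunflower seed,other pulses and seeds,legumes_nuts_seeds
2558,Rape and Mustardseed,other pulses and seeds,legumes_nuts_seeds
2559,Cottonseed,other pulses and seeds,legumes_nuts_seeds
2560,Coconuts - Incl Copra,coconuts,legumes_nuts_seeds
2561,Sesame seed,other pulses and seeds,legumes_nuts_seeds
2563,Olives (including preserved),olives,legumes_nuts_seeds
2551,Nuts and products,nuts,legumes_nuts_seeds
2571,Soyabean Oil,soybean oil,oils_fats
2572,Groundnut Oil,other vegetable oils,oils_fats
2573,Sunflowerseed Oil,sunflower oil,oils_fats
2574,Rape and Mustard Oil,other vegetable oils,oils_fats
2575,Cottonseed Oil,other vegetable oils,oils_fats
2576,Palmkernel Oil,palm oil,oils_fats
2577,Palm Oil,palm oil,oils_fats
2578,Coconut Oil,other vegetable oils,oils_fats
2579,Sesameseed Oil,other vegetable oils,oils_fats
2580,Olive Oil,olive oil,oils_fats
2581,Ricebran Oil,other vegetable oils,oils_fats
2582,Maize Germ Oil,other vegetable oils,oils_fats
2586,"Oilcrops Oil, Other",other vegetable oils,oils_fats
2737,"Fats, Animals, Raw",animal fats,oils_fats
2740,Butter Ghee,animal fats,oils_fats
2741,Cream,animal fats,oils_fats
2541,Sugar non-centrifugal,sugar,SUGAR
2542,Sugar (Raw Equivalent),sugar,SUGAR
2543,"Sweeteners, Other",sweeteners,SUGAR
2745,Honey,sweeteners,SUGAR
2630,Coffee and products,stimulants,EXCLUDED
2633,Cocoa Beans and products,stimulants,EXCLUDED
2635,Tea (including mate),stimulants,EXCLUDED
2640,Pepper,spices,EXCLUDED
2641,Pimento,spices,EXCLUDED
2642,Cloves,spices,EXCLUDED
2645,"Spices, Other",spices,EXCLUDED
2655,Wine,alcoholic beverages,EXCLUDED
2656,Beer,alcoholic beverages,EXCLUDED
2657,"Beverages, Fermented",alcoholic beverages,EXCLUDED
2658,"Beverages, Alcoholic",alcoholic beverages,EXCLUDED
2680,Infant food,infant food,EXCLUDED
2899,Miscellaneous,miscellaneous,EXCLUDED
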