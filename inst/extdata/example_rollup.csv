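subcategory,category
Baby Food,Baby Food
Dairy,Dairy
Ready Meals,Ready Meals and Soup
Soup,Ready Meals and Soup
"Sauces, Dressings, and Condiments","Sauces, Dressings, Spreads, and Dips"
Sweet Spreads,"Sauces, Dressings, Spreads, and Dips"
Confectionery,Sweet Snacks
Ice Cream and Frozen Desserts,Sweet Snacks
"Sweet Biscuits, Snack Bars, and Fruit Snacks",Sweet Snacks
Savory Snacks,Savory Snacks
Baked Goods,Baked Goods
Breakfast Cereals,Cereal and Grain Products
"Rice, Pasta, and Noodles",Cereal and Grain Products
Processed Fruit and Vegetables,Processed Fruit and Vegetables
Processed Meat,Processed Meat
Meat Substitutes,Meat Substitutes
Processed Seafood,Processed Seafood
Carbonates,Soft Drinks and Juice
Concentrates,Soft Drinks and Juice
Energy Drinks,Soft Drinks and Juice
Juice,Soft Drinks and Juice
Sports Drinks,Soft Drinks and Juice
Ready-to-Drink Coffee,Coffee and Tea
Ready-to-Drink Tea,Coffee and Tea
Bottled Water,Water and Functional Beverages
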